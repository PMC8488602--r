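condition,reaction,bound,value
Standard control,EX_CO2_E,lb,-10
Standard control,EX_GLYC_E,lb,0
Standard control,EX_SO4_E,lb,-1000
Standard control,EX_NO3_E,lb,-1000
Standard control,EX_NH4_E,lb,-1000
Standard control,EX_UREA_E,lb,-1000
Standard control,EX_PHOTON_E,lb,-0.065
Standard control,EX_O2_E,lb,-1000
Standard control,EX_FE_E,lb,-1000
Standard control,EX_PHOTON_E,ub,1000
Standard control,EX_O2_E,ub,1000
Darkoxic,EX_CO2_E,lb,-10
Darkoxic,EX_GLYC_E,lb,0
Darkoxic,EX_SO4_E,lb,-1000
Darkoxic,EX_NO3_E,lb,-1000
Darkoxic,EX_NH4_E,lb,-1000
Darkoxic,EX_UREA_E,lb,-1000
Darkoxic,EX_PHOTON_E,lb,-0.003
Darkoxic,EX_O2_E,lb,-1000
Darkoxic,EX_FE_E,lb,-1000
Darkoxic,EX_PHOTON_E,ub,1000
Darkoxic,EX_O2_E,ub,1000
Darkanoxic,EX_CO2_E,lb,-10
Darkanoxic,EX_GLYC_E,lb,0
Darkanoxic,EX_SO4_E,lb,-1000
Darkanoxic,EX_NO3_E,lb,-1000
Darkanoxic,EX_NH4_E,lb,-1000
Darkanoxic,EX_UREA_E,lb,-1000
Darkanoxic,EX_PHOTON_E,lb,-0.003
Darkanoxic,EX_O2_E,lb,-0.01
Darkanoxic,EX_FE_E,lb,-1000
Darkanoxic,EX_PHOTON_E,ub,1000
Darkanoxic,EX_O2_E,ub,-0.01
Highlight,EX_CO2_E,lb,-10
Highlight,EX_GLYC_E,lb,0
Highlight,EX_SO4_E,lb,-1000
Highlight,EX_NO3_E,lb,-1000
Highlight,EX_NH4_E,lb,-1000
Highlight,EX_UREA_E,lb,-1000
Highlight,EX_PHOTON_E,lb,-0.234
Highlight,EX_O2_E,lb,-1000
Highlight,EX_FE_E,lb,-1000
Highlight,EX_PHOTON_E,ub,1000
Highlight,EX_O2_E,ub,1000
OD04,EX_CO2_E,lb,-10
OD04,EX_GLYC_E,lb,0
OD04,EX_SO4_E,lb,-1000
OD04,EX_NO3_E,lb,-1000
OD04,EX_NH4_E,lb,-1000
OD04,EX_UREA_E,lb,-1000
OD04,EX_PHOTON_E,lb,-0.114
OD04,EX_O2_E,lb,-1000
OD04,EX_FE_E,lb,-1000
OD04,EX_PHOTON_E,ub,1000
OD04,EX_O2_E,ub,1000
OD10,EX_CO2_E,lb,-10
OD10,EX_GLYC_E,lb,0
OD10,EX_SO4_E,lb,-1000
OD10,EX_NO3_E,lb,-1000
OD10,EX_NH4_E,lb,-1000
OD10,EX_UREA_E,lb,-1000
OD10,EX_PHOTON_E,lb,-0.045
OD10,EX_O2_E,lb,-1000
OD10,EX_FE_E,lb,-1000
OD10,EX_PHOTON_E,ub,1000
OD10,EX_O2_E,ub,1000
OD30,EX_CO2_E,lb,-10
OD30,EX_GLYC_E,lb,0
OD30,EX_SO4_E,lb,-1000
OD30,EX_NO3_E,lb,-1000
OD30,EX_NH4_E,lb,-1000
OD30,EX_UREA_E,lb,-1000
OD30,EX_PHOTON_E,lb,-0.008
OD30,EX_O2_E,lb,-1000
OD30,EX_FE_E,lb,-1000
OD30,EX_PHOTON_E,ub,1000
OD30,EX_O2_E,ub,1000
OD50,EX_CO2_E,lb,-10
OD50,EX_GLYC_E,lb,0
OD50,EX_SO4_E,lb,-1000
OD50,EX_NO3_E,lb,-1000
OD50,EX_NH4_E,lb,-1000
OD50,EX_UREA_E,lb,-1000
OD50,EX_PHOTON_E,lb,-0.004
OD50,EX_O2_E,lb,-1000
OD50,EX_FE_E,lb,-1000
OD50,EX_PHOTON_E,ub,1000
OD50,EX_O2_E,ub,1000
lowO2,EX_CO2_E,lb,-10
lowO2,EX_GLYC_E,lb,0
lowO2,EX_SO4_E,lb,-1000
lowO2,EX_NO3_E,lb,-1000
lowO2,EX_NH4_E,lb,-1000
lowO2,EX_UREA_E,lb,-1000
lowO2,EX_PHOTON_E,lb,-0.065
lowO2,EX_O2_E,lb,-0.01
lowO2,EX_FE_E,lb,-1000
lowO2,EX_PHOTON_E,ub,1000
lowO2,EX_O2_E,ub,-0.01
lowCO2,EX_CO2_E,lb,-0.01
lowCO2,EX_GLYC_E,lb,0
lowCO2,EX_SO4_E,lb,-1000
lowCO2,EX_NO3_E,lb,-1000
lowCO2,EX_NH4_E,lb,-1000
lowCO2,EX_UREA_E,lb,-1000
lowCO2,EX_PHOTON_E,lb,-0.065
lowCO2,EX_O2_E,lb,-1000
lowCO2,EX_FE_E,lb,-1000
lowCO2,EX_PHOTON_E,ub,1000
lowCO2,EX_O2_E,ub,1000
Nlim,EX_CO2_E,lb,-10
Nlim,EX_GLYC_E,lb,0
Nlim,EX_SO4_E,lb,-1000
Nlim,EX_NO3_E,lb,-0.01
Nlim,EX_NH4_E,lb,-1000
Nlim,EX_UREA_E,lb,-1000
Nlim,EX_PHOTON_E,lb,-0.065
Nlim,EX_O2_E,lb,-1000
Nlim,EX_FE_E,lb,-1000
Nlim,EX_PHOTON_E,ub,1000
Nlim,EX_O2_E,ub,1000
Slim,EX_CO2_E,lb,-10
Slim,EX_GLYC_E,lb,0
Slim,EX_SO4_E,lb,-0.01
Slim,EX_NO3_E,lb,-1000
Slim,EX_NH4_E,lb,-1000
Slim,EX_UREA_E,lb,-1000
Slim,EX_PHOTON_E,lb,-0.065
Slim,EX_O2_E,lb,-1000
Slim,EX_FE_E,lb,-1000
Slim,EX_PHOTON_E,ub,1000
Slim,EX_O2_E,ub,1000
Plim,EX_CO2_E,lb,-10
Plim,EX_GLYC_E,lb,0
Plim,EX_SO4_E,lb,-1000
Plim,EX_NO3_E,lb,-1000
Plim,EX_NH4_E,lb,-1000
Plim,EX_UREA_E,lb,-1000
Plim,EX_PHOTON_E,lb,-0.065
Plim,EX_O2_E,lb,-1000
Plim,EX_FE_E,lb,-1000
Plim,EX_PHOTON_E,ub,1000
Plim,EX_O2_E,ub,1000
Felim,EX_CO2_E,lb,-10
Felim,EX_GLYC_E,lb,0
Felim,EX_SO4_E,lb,-1000
Felim,EX_NO3_E,lb,-1000
Felim,EX_NH4_E,lb,-1000
Felim,EX_UREA_E,lb,-1000
Felim,EX_PHOTON_E,lb,-0.065
Felim,EX_O2_E,lb,-1000
Felim,EX_FE_E,lb,-0.01
Felim,EX_PHOTON_E,ub,1000
Felim,EX_O2_E,ub,1000
Nitrate,EX_CO2_E,lb,-10
Nitrate,EX_GLYC_E,lb,0
Nitrate,EX_SO4_E,lb,-1000
Nitrate,EX_NO3_E,lb,-12
Nitrate,EX_NH4_E,lb,-1000
Nitrate,EX_UREA_E,lb,-1000
Nitrate,EX_PHOTON_E,lb,-0.065
Nitrate,EX_O2_E,lb,-1000
Nitrate,EX_FE_E,lb,-1000
Nitrate,EX_PHOTON_E,ub,1000
Nitrate,EX_O2_E,ub,1000
Ammonia,EX_CO2_E,lb,-10
Ammonia,EX_GLYC_E,lb,0
Ammonia,EX_SO4_E,lb,-1000
Ammonia,EX_NO3_E,lb,0
Ammonia,EX_NH4_E,lb,-10
Ammonia,EX_UREA_E,lb,-1000
Ammonia,EX_PHOTON_E,lb,-0.065
Ammonia,EX_O2_E,lb,-1000
Ammonia,EX_FE_E,lb,-1000
Ammonia,EX_PHOTON_E,ub,1000
Ammonia,EX_O2_E,ub,1000
Urea,EX_CO2_E,lb,-10
Urea,EX_GLYC_E,lb,0
Urea,EX_SO4_E,lb,-1000
Urea,EX_NO3_E,lb,0
Urea,EX_NH4_E,lb,-1000
Urea,EX_UREA_E,lb,-10
Urea,EX_PHOTON_E,lb,-0.065
Urea,EX_O2_E,lb,-1000
Urea,EX_FE_E,lb,-1000
Urea,EX_PHOTON_E,ub,1000
Urea,EX_O2_E,ub,1000
Heatshock,EX_CO2_E,lb,-10
Heatshock,EX_GLYC_E,lb,0
Heatshock,EX_SO4_E,lb,-1000
Heatshock,EX_NO3_E,lb,-1000
Heatshock,EX_NH4_E,lb,-1000
Heatshock,EX_UREA_E,lb,-1000
Heatshock,EX_PHOTON_E,lb,-0.065
Heatshock,EX_O2_E,lb,-1000
Heatshock,EX_FE_E,lb,-1000
Heatshock,EX_PHOTON_E,ub,1000
Heatshock,EX_O2_E,ub,1000
T22,EX_CO2_E,lb,-10
T22,EX_GLYC_E,lb,0
T22,EX_SO4_E,lb,-1000
T22,EX_NO3_E,lb,-1000
T22,EX_NH4_E,lb,-1000
T22,EX_UREA_E,lb,-1000
T22,EX_PHOTON_E,lb,-0.065
T22,EX_O2_E,lb,-1000
T22,EX_FE_E,lb,-1000
T22,EX_PHOTON_E,ub,1000
T22,EX_O2_E,ub,1000
T30,EX_CO2_E,lb,-10
T30,EX_GLYC_E,lb,0
T30,EX_SO4_E,lb,-1000
T30,EX_NO3_E,lb,-1000
T30,EX_NH4_E,lb,-1000
T30,EX_UREA_E,lb,-1000
T30,EX_PHOTON_E,lb,-0.065
T30,EX_O2_E,lb,-1000
T30,EX_FE_E,lb,-1000
T30,EX_PHOTON_E,ub,1000
T30,EX_O2_E,ub,1000
Oxstress,EX_CO2_E,lb,-10
Oxstress,EX_GLYC_E,lb,0
Oxstress,EX_SO4_E,lb,-1000
Oxstress,EX_NO3_E,lb,-1000
Oxstress,EX_NH4_E,lb,-1000
Oxstress,EX_UREA_E,lb,-1000
Oxstress,EX_PHOTON_E,lb,-0.065
Oxstress,EX_O2_E,lb,-1000
Oxstress,EX_FE_E,lb,-1000
Oxstress,EX_PHOTON_E,ub,1000
Oxstress,EX_O2_E,ub,1000
Mixotrophic,EX_CO2_E,lb,-10
Mixotrophic,EX_GLYC_E,lb,-10
Mixotrophic,EX_SO4_E,lb,-1000
Mixotrophic,EX_NO3_E,lb,-1000
Mixotrophic,EX_NH4_E,lb,-1000
Mixotrophic,EX_UREA_E,lb,-1000
Mixotrophic,EX_PHOTON_E,lb,-0.065
Mixotrophic,EX_O2_E,lb,-1000
Mixotrophic,EX_FE_E,lb,-1000
Mixotrophic,EX_PHOTON_E,ub,1000
Mixotrophic,EX_O2_E,ub,1000
Lowsalt,EX_CO2_E,lb,-10
Lowsalt,EX_GLYC_E,lb,0
Lowsalt,EX_SO4_E,lb,-1000
Lowsalt,EX_NO3_E,lb,-1000
Lowsalt,EX_NH4_E,lb,-1000
Lowsalt,EX_UREA_E,lb,-1000
Lowsalt,EX_PHOTON_E,lb,-0.065
Lowsalt,EX_O2_E,lb,-1000
Lowsalt,EX_FE_E,lb,-1000
Lowsalt,EX_PHOTON_E,ub,1000
Lowsalt,EX_O2_E,ub,1000
Highsalt,EX_CO2_E,lb,-10
Highsalt,EX_GLYC_E,lb,0
Highsalt,EX_SO4_E,lb,-1000
Highsalt,EX_NO3_E,lb,-1000
Highsalt,EX_NH4_E,lb,-1000
Highsalt,EX_UREA_E,lb,-1000
Highsalt,EX_PHOTON_E,lb,-0.065
Highsalt,EX_O2_E,lb,-1000
Highsalt,EX_FE_E,lb,-1000
Highsalt,EX_PHOTON_E,ub,1000
Highsalt,EX_O2_E,ub,1000
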