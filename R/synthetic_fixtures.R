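# Self-contained toy inputs: a small mass-balanced photoautotroph-like
# network, RPKM-style transcript tables, the packaged condition-bounds table,
# and the growth-rate listing -- everything the pipeline needs without
# downloads.

#' The 23 experimental growth-condition labels
#'
#' Order matches the transcript fold-change matrix; the standard control is
#' appended as row 24 of flux matrices.
#'
#' @return character vector of 23 condition names.
#' @export
condition_names <- function() {
  c("Darkoxic", "Darkanoxic", "Highlight", "OD04", "OD10", "OD30", "OD50",
    "lowO2", "lowCO2", "Nlim", "Slim", "Plim", "Felim", "Nitrate", "Ammonia",
    "Urea", "Heatshock", "T22", "T30", "Oxstress", "Mixotrophic", "Lowsalt",
    "Highsalt")
}

#' Build the bundled toy metabolic model
#'
#' A 14-metabolite, 21-reaction photoautotroph-like network: nutrient
#' exchanges (CO2, glycerol, SO4, NO3, NH4, urea, photon, O2, Fe), two
#' photosystem-like light reactions, carbon fixation, glycerol assimilation,
#' a pair of parallel redundant glycolytic steps (exercising the L2
#' tie-break), nitrogen assimilation, respiration, a biomass sink and an ATP
#' maintenance reaction. GPR rules include AND/OR combinations, one
#' parenthesized rule, and transcript-suffixed gene ids; subsystem
#' annotations include raw synonyms and one multi-subsystem name so the
#' curation steps are exercised on realistic input. Baseline exchange bounds
#' are the standard-control row of the packaged condition table.
#'
#' @param curate apply [normalize_subsystem_names()] and
#'   [split_multi_subsystems()] (default TRUE).
#' @return A [metabolic_model()].
#' @export
make_toy_model <- function(curate = TRUE) {
  rx <- list(
    #      id           name                                   equation                                        lb     ub     grRule                                subsystem
    list("EX_CO2_E",    "CO2 exchange",                        "co2 ->",                                       -10,   1000, "",                                    "Exchange Reaction"),
    list("EX_GLYC_E",   "Glycerol exchange",                   "glyc ->",                                       0,    1000, "",                                    "Exchange Reaction"),
    list("EX_SO4_E",    "Sulfate exchange",                    "so4 ->",                                       -1000, 1000, "",                                    "Exchange Reaction"),
    list("EX_NO3_E",    "Nitrate exchange",                    "no3 ->",                                       -1000, 1000, "",                                    "Exchange Reaction"),
    list("EX_NH4_E",    "Ammonium exchange",                   "nh4 ->",                                       -1000, 1000, "",                                    "Exchange Reaction"),
    list("EX_UREA_E",   "Urea exchange",                       "urea ->",                                      -1000, 1000, "",                                    "Exchange Reaction"),
    list("EX_PHOTON_E", "Photon exchange",                     "photon ->",                                    -0.065, 1000, "",                                   "Exchange Reaction"),
    list("EX_O2_E",     "O2 exchange",                         "o2 ->",                                        -1000, 1000, "",                                    "Exchange Reaction"),
    list("EX_FE_E",     "Fe3+ exchange",                       "fe ->",                                        -1000, 1000, "",                                    "Exchange Reaction"),
    list("PSII",        "photosystem II reaction",             "photon -> 0.8 atp + 0.3 o2",                    0,    1000, "(SYN0001.1 or SYN0002.1) and SYN0003.1", "Photosynthesis"),
    list("PSI",         "Photosystem I Reaction (cytochrome c6)", "photon -> nadph",                            0,    1000, "SYN0004.1 and SYN0005.1",             "Photosynthesis"),
    list("RBC",         "CO2 fixation (RuBisCO)",              "co2 + 2 atp + 2 nadph -> c3",                   0,    1000, "SYN0006.1 and SYN0007.1",             "Carbohydrate Metabolism"),
    list("GLYK",        "Glycerol assimilation",               "glyc + atp -> c3 + nadph",                      0,    1000, "SYN0008.1",                           "Lipid and Cell Wall Metabolism"),
    list("PGA",         "Phosphoglycerate route A",            "c3 -> cc",                                      0,    1000, "SYN0009.1",                           "Glycolysis"),
    list("PGB",         "Phosphoglycerate route B",            "c3 -> cc",                                      0,    1000, "SYN0010.1",                           "Glycolysis"),
    list("NIR",         "Nitrate reductase",                   "no3 + 0.5 nadph -> nh4",                        0,    1000, "SYN0011.1",                           "Amino Acid Metabolisms"),
    list("URE",         "Urease",                              "urea -> 2 nh4 + co2",                           0,    1000, "SYN0012.1 and SYN0013.1",             "Amino Acid Metabolism"),
    list("GS",          "Glutamine synthetase route",          "nh4 + cc + atp + 0.2 so4 + 0.01 fe -> aa",      0,    1000, "SYN0014.1 and SYN0015.1 or SYN0016.1", "Amino acid metabolism"),
    list("RESP",        "Respiration",                         "cc + o2 -> 2 atp",                              0,    1000, "SYN0017.1",                           "Oxidative phosphorylation"),
    list("RTO",         "Respiratory terminal oxidase",        "o2 + 0.2 nadph -> 0.1 atp",                     0,    1000, "SYN0018.1",                           "Oxidative phosphorylation"),
    list("BIOMASS",     "Biomass",                             "0.5 aa + 0.5 cc + 2 atp ->",                    0,    1000, "",                                    "Biomass"),
    list("ATPM",        "ATP maintenance requirment",          "atp ->",                                        0,    1000, "",                                    "None"))
  df <- data.frame(id = vapply(rx, `[[`, "", 1), name = vapply(rx, `[[`, "", 2),
                   equation = vapply(rx, `[[`, "", 3),
                   lb = vapply(rx, `[[`, 0, 4), ub = vapply(rx, `[[`, 0, 5),
                   grRule = vapply(rx, `[[`, "", 6),
                   subsystems = vapply(rx, `[[`, "", 7),
                   stringsAsFactors = FALSE)
  eqs <- lapply(df$equation, parse_reaction_equation)
  mets <- unique(unlist(lapply(eqs, names)))
  S <- matrix(0, length(mets), nrow(df), dimnames = list(mets, df$id))
  for (j in seq_along(eqs)) S[names(eqs[[j]]), j] <- eqs[[j]]
  model <- metabolic_model(S, df$lb, df$ub, df$id, df$name, mets,
                           genes = toy_gene_ids(), grRules = df$grRule,
                           subSystems = as.list(df$subsystems))
  if (curate) {
    model <- normalize_subsystem_names(model)
    model <- split_multi_subsystems(model)
  }
  model
}

toy_gene_ids <- function() paste0("SYN", sprintf("%04d", 1:18), ".1")

#' Default per-condition expression effects of the synthetic transcriptome
#'
#' Multiplicative expression shifts emulating the biology of each growth
#' condition: photosystem genes fall ~4-fold in darkness and double in high
#' light, glycerol kinase rises 4-fold under mixotrophy, nitrate assimilation
#' rises under nitrogen limitation and falls when reduced nitrogen is
#' supplied. Conditions without an entry are unshifted (pure noise around the
#' control).
#'
#' @return named list: condition -> named numeric vector of gene effects
#'   (dataset gene ids).
#' @export
default_condition_effects <- function() {
  ps <- paste0("SYN", sprintf("%04d", 1:5))
  list(
    Darkoxic    = stats::setNames(rep(0.25, 5), ps),
    Darkanoxic  = stats::setNames(rep(0.25, 5), ps),
    Highlight   = stats::setNames(rep(2, 5), ps),
    lowCO2      = c(SYN0006 = 1.5, SYN0007 = 1.5),
    Nlim        = c(SYN0011 = 3),
    Ammonia     = c(SYN0011 = 0.5),
    Urea        = c(SYN0011 = 0.5, SYN0012 = 2, SYN0013 = 2),
    Mixotrophic = c(SYN0008 = 4))
}

#' Generate RPKM-like transcript tables
#'
#' Emulates the two-study layout of the protocol's transcriptome: dataset 1
#' carries the first 16 conditions, dataset 2 the remaining 7, each with 3
#' standard-control replicate columns. Values are
#' `baseline * condition_effect * lognormal noise`; gene ids match the toy
#' model's after suffix truncation. Positivity motivates the lognormal noise;
#' the default coefficient of variation is 0.1.
#'
#' @param model a [metabolic_model()] supplying the gene list.
#' @param seed RNG seed (fixed seed gives byte-identical tables).
#' @param effects condition effect list (default
#'   [default_condition_effects()]).
#' @param noise_cv lognormal noise coefficient of variation (default 0.1).
#' @param baseline_meanlog mean log baseline RPKM (default log(100)).
#' @return list with data.frames `dataset1` and `dataset2` (columns: gene_id,
#'   cog_category, 3 controls, condition columns).
#' @export
make_synthetic_transcriptome <- function(model, seed = 1,
                                         effects = default_condition_effects(),
                                         noise_cv = 0.1,
                                         baseline_meanlog = log(100)) {
  genes <- truncate_gene_ids(model$genes)
  conds <- condition_names()
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  baseline <- stats::rlnorm(length(genes), baseline_meanlog, 1)
  noisy <- function(values) values * stats::rlnorm(length(values), 0, sdlog)
  cond_column <- function(cond) {
    eff <- rep(1, length(genes))
    if (cond %in% names(effects)) {
      e <- effects[[cond]]
      ix <- match(names(e), genes)
      eff[ix[!is.na(ix)]] <- e[!is.na(ix)]
    }
    noisy(baseline * eff)
  }
  build <- function(cond_subset) {
    df <- data.frame(gene_id = genes,
                     cog_category = rep(c("Energy production", "Metabolism",
                                          "Information processing"),
                                        length.out = length(genes)),
                     stringsAsFactors = FALSE)
    for (k in 1:3) df[[paste0("control_", k)]] <- noisy(baseline)
    for (cond in cond_subset) df[[cond]] <- cond_column(cond)
    df
  }
  list(dataset1 = build(conds[1:16]), dataset2 = build(conds[17:23]))
}

#' Packaged condition-bounds table
#'
#' Loads the bundled exchange-bound table (24 growth conditions: 23
#' experimental plus the standard control) mapped onto the toy model's
#' exchange reactions and returns one [condition_spec()] per condition. The
#' magnitudes reproduce the protocol's published per-condition uptake and
#' secretion limits (photon lower bound -0.065 in the standard control,
#' glycerol -10 under mixotrophy, nitrate -12 in the nitrate condition, O2
#' capped at -0.01 under anoxia, and so on).
#'
#' @param path optional override path to a bounds CSV with columns
#'   `condition`, `reaction`, `bound` (`lb`/`ub`), `value`.
#' @return named list of [condition_spec()] (control included).
#' @export
builtin_condition_bounds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "condition_bounds.csv", package = "omicflux")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "reaction", "bound", "value") %in% names(tab)))
  specs <- lapply(split(tab, factor(tab$condition, levels = unique(tab$condition))),
                  function(rows) {
    lbs <- rows[rows$bound == "lb", ]
    ubs <- rows[rows$bound == "ub", ]
    condition_spec(rows$condition[1],
                   lb_overrides = stats::setNames(lbs$value, lbs$reaction),
                   ub_overrides = stats::setNames(ubs$value, ubs$reaction))
  })
  specs[unique(tab$condition)]
}

#' Growth rates for the regression subset
#'
#' The 12 growth conditions (standard control first) with growth rates
#' available from the source cultivation studies, as used by the LASSO and
#' correlation analyses.
#'
#' @return data.frame with columns `condition` (matrix row label), `display`
#'   (printed condition name) and `growth_rate` (1/h).
#' @export
builtin_growth_rates <- function() {
  data.frame(
    condition = c("Standard control", "Nlim", "Slim", "Plim", "Nitrate",
                  "Ammonia", "Urea", "T22", "T30", "Mixotrophic", "Lowsalt",
                  "Highsalt"),
    display = c("Standard Control", "N-limited", "S-limited", "P-limited",
                "Nitrate", "Ammonia", "Urea", "22C", "30C", "Mixotrophic",
                "Low salt", "High salt"),
    growth_rate = c(0.075, 0.046153846, 0.05, 0.035294118, 0.173286795,
                    0.266595069, 0.266595069, 0.038659794, 0.068807339,
                    0.089285714, 0.076530612, 0.027777778),
    stringsAsFactors = FALSE)
}
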