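# Independent oracles and shared fixtures for the test suite.

# LP oracle: scipy.optimize.linprog (HiGHS), entirely independent of the
# package's interior-point implementation.
scipy_lp <- function(cvec, A, b, lb, ub, maximize = FALSE) {
  dir <- withr::local_tempdir()
  inp <- file.path(dir, "in.json"); outp <- file.path(dir, "out.json")
  jsonlite::write_json(list(c = if (maximize) -cvec else cvec,
                            A = unname(as.matrix(A)), b = b, lb = lb, ub = ub),
                       inp, digits = NA, auto_unbox = FALSE)
  script <- sprintf('
import json, numpy as np
from scipy.optimize import linprog
d = json.load(open("%s"))
res = linprog(np.array(d["c"]), A_eq=np.array(d["A"]), b_eq=np.array(d["b"]),
              bounds=list(zip(d["lb"], d["ub"])), method="highs")
json.dump({"status": int(res.status),
           "fun": None if res.fun is None else float(res.fun),
           "x": None if res.x is None else res.x.tolist()}, open("%s","w"))
', inp, outp)
  sf <- file.path(dir, "lp.py"); writeLines(script, sf)
  stopifnot(system2("python", sf, stdout = FALSE, stderr = FALSE) == 0)
  out <- jsonlite::read_json(outp, simplifyVector = TRUE)
  if (!is.null(out$fun) && maximize) out$fun <- -out$fun
  out
}

# QP oracle: scipy SLSQP for min ||v||^2 over the optimum-fixed polytope.
scipy_min_norm <- function(A, b, lb, ub, cut_index, cut_value) {
  dir <- withr::local_tempdir()
  inp <- file.path(dir, "in.json"); outp <- file.path(dir, "out.json")
  jsonlite::write_json(list(A = unname(as.matrix(A)), b = b, lb = lb, ub = ub,
                            ci = cut_index - 1L, cv = cut_value),
                       inp, digits = NA, auto_unbox = FALSE)
  script <- sprintf('
import json, numpy as np
from scipy.optimize import minimize
d = json.load(open("%s"))
A = np.array(d["A"]); b = np.array(d["b"])
ci = [int(i) for i in d["ci"]]; cv = np.array(d["cv"])
n = A.shape[1]
cons = [{"type": "eq", "fun": lambda v: A @ v - b,
         "jac": lambda v: A},
        {"type": "ineq", "fun": lambda v: v[ci] - cv}]
x0 = np.clip(np.zeros(n), d["lb"], d["ub"])
res = minimize(lambda v: float(v @ v), x0, jac=lambda v: 2*v,
               bounds=list(zip(d["lb"], d["ub"])), constraints=cons,
               method="SLSQP", options={"maxiter": 1000, "ftol": 1e-10})
x = res.x
feas = max(float(np.max(np.abs(A @ x - b))),
           float(np.max(np.maximum(cv - x[ci], 0))),
           float(np.max(np.maximum(np.array(d["lb"]) - x, 0))),
           float(np.max(np.maximum(x - np.array(d["ub"]), 0))))
json.dump({"x": x.tolist(), "feas": feas}, open("%s","w"))
', inp, outp)
  sf <- file.path(dir, "qp.py"); writeLines(script, sf)
  stopifnot(system2("python", sf, stdout = FALSE, stderr = FALSE) == 0)
  jsonlite::read_json(outp, simplifyVector = TRUE)
}

# tiny <=15-reaction network for solver oracle tests:
# R1: -> A (capped source), R2/R3: parallel A -> B, R4: B -> (primary),
# R5: A -> (secondary drain)
tiny_lp_fixture <- function() {
  S <- matrix(0, 2, 5, dimnames = list(c("A", "B"), paste0("R", 1:5)))
  S["A", 1] <- 1
  S["A", 2] <- -1; S["B", 2] <- 1
  S["A", 3] <- -1; S["B", 3] <- 1
  S["B", 4] <- -1
  S["A", 5] <- -1
  metabolic_model(S, lb = rep(0, 5), ub = c(10, 8, 8, 100, 3),
                  rxns = colnames(S))
}

# string-splitting GPR evaluator, independent of the tokenizer/parser path:
# split on top-level "or" (MAX), then top-level "and" (MIN), recursing into
# parentheses
brute_gpr_eval <- function(rule, x) {
  rule <- trimws(rule)
  if (!nzchar(rule)) return(1)
  split_top <- function(s, word) {
    depth <- 0; parts <- character(); last <- 1
    i <- 1
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "(") depth <- depth + 1
      if (ch == ")") depth <- depth - 1
      if (depth == 0 && i + nchar(word) + 1 <= n + 1) {
        seg <- substr(s, i, i + nchar(word) + 1)
        if (tolower(seg) == paste0(" ", word, " ")) {
          parts <- c(parts, substr(s, last, i - 1))
          last <- i + nchar(word) + 2
          i <- i + nchar(word) + 1
        }
      }
      i <- i + 1
    }
    c(parts, substr(s, last, nchar(s)))
  }
  ors <- split_top(rule, "or")
  if (length(ors) > 1) return(max(vapply(ors, brute_gpr_eval, 0, x = x)))
  ands <- split_top(rule, "and")
  if (length(ands) > 1) return(min(vapply(ands, brute_gpr_eval, 0, x = x)))
  s <- trimws(rule)
  if (startsWith(s, "(") && endsWith(s, ")"))
    return(brute_gpr_eval(substr(s, 2, nchar(s) - 1), x))
  x[[s]]
}

# random GPR rule over a small gene alphabet
random_gpr_rule <- function(genes, depth = 0) {
  if (depth > 2 || stats::runif(1) < 0.4) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  lhs <- random_gpr_rule(genes, depth + 1)
  rhs <- random_gpr_rule(genes, depth + 1)
  out <- paste(lhs, op, rhs)
  if (stats::runif(1) < 0.3) out <- paste0("(", out, ")")
  out
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# transcript fold-change matrix used by several suites
toy_transcript_fc <- function(model, seed = 1) {
  tx <- make_synthetic_transcriptome(model, seed = seed)
  to_fc <- function(df) {
    num <- df[vapply(df, is.numeric, TRUE)]
    m <- as.matrix(num); rownames(m) <- df$gene_id
    ctrl <- grep("^control", colnames(m))
    rpkm_to_foldchange(m, ctrl, setdiff(seq_len(ncol(m)), ctrl))
  }
  t(cbind(to_fc(tx$dataset1), to_fc(tx$dataset2)))
}
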