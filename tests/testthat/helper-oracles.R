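# Independent oracles used by the tests.
#
# py_fba_batch() solves a batch of FBA-style LPs with scipy.optimize.linprog
# (HiGHS) through the system python: an implementation completely independent
# of the package's simplex. Each scenario is a set of reactions to close on
# top of the base model.

PY_LP_SCRIPT <- '
import json, sys
import numpy as np
from scipy.optimize import linprog

spec = json.load(open(sys.argv[1]))
S = np.array(spec["S"]); lb = np.array(spec["lb"]); ub = np.array(spec["ub"])
obj = np.array(spec["obj"])
res = []
for sc in spec["scenarios"]:
    l, u = lb.copy(), ub.copy()
    for i in sc.get("close", []):
        l[i] = 0.0; u[i] = 0.0
    for i, v in sc.get("lb", {}).items():
        l[int(i)] = v
    for i, v in sc.get("ub", {}).items():
        u[int(i)] = v
    sense = -1.0 if sc.get("maximize", True) else 1.0
    r = linprog(sense * obj, A_eq=S, b_eq=np.zeros(S.shape[0]),
                bounds=list(zip(l, u)), method="highs")
    res.append({"status": "optimal" if r.status == 0 else "infeasible",
                "objective": float(np.dot(obj, r.x)) if r.status == 0 else None,
                "sum_abs": float(np.abs(r.x).sum()) if r.status == 0 else None})
json.dump(res, open(sys.argv[2], "w"))
'

# scenarios: list of lists with elements `close` (reaction ids), `lb`/`ub`
# (named numeric overrides), `maximize`, `objective` defaulting to the model
# objective. Returns a numeric vector of objective values (NA = infeasible).
py_fba_batch <- function(model, scenarios = list(list()), objective = model$objective) {
  S <- stoich_matrix(model)
  obj <- as.numeric(colnames(S) == objective)
  idx0 <- function(ids) as.integer(match(ids, colnames(S)) - 1L)
  spec <- list(
    S = lapply(seq_len(nrow(S)), function(i) as.list(unname(S[i, ]))),
    lb = as.list(pmax(model$rxns$lb, -1000)),
    ub = as.list(pmin(model$rxns$ub, 1000)),
    obj = as.list(obj),
    scenarios = lapply(scenarios, function(sc) {
      out <- list(maximize = isTRUE(sc$maximize %||% TRUE))
      if (length(sc$close)) out$close <- as.list(idx0(sc$close))
      if (length(sc$lb)) out$lb <- stats::setNames(as.list(unname(sc$lb)), idx0(names(sc$lb)))
      if (length(sc$ub)) out$ub <- stats::setNames(as.list(unname(sc$ub)), idx0(names(sc$ub)))
      out
    })
  )
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  fscript <- tempfile(fileext = ".py")
  writeLines(PY_LP_SCRIPT, fscript)
  jsonlite::write_json(spec, fin, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(fscript, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) stop("python LP oracle failed: ", paste(status, collapse = "\n"))
  res <- jsonlite::read_json(fout)
  data.frame(
    objective = vapply(res, function(r)
      if (r$status == "optimal") r$objective else NA_real_, 0.0),
    sum_abs = vapply(res, function(r)
      if (r$status == "optimal") r$sum_abs else NA_real_, 0.0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent GPR boolean oracle: textual substitution into an R expression
gpr_eval_oracle <- function(rule, knocked_out) {
  genes <- gpr_genes(parse_gpr(rule))
  env <- as.list(stats::setNames(!(genes %in% knocked_out), genes))
  expr <- gsub("\\band\\b", "&", gsub("\\bor\\b", "|", rule, ignore.case = TRUE),
               ignore.case = TRUE)
  isTRUE(eval(parse(text = expr), envir = env))
}
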