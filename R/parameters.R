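# Parameter roster for the 17-state leukopoiesis model.
#
# 51 named scalars: 7 death rates fixed from literature ranges, 44 flagged
# "sampled" (uncertain). The four cancer parameters default to their monocyte
# counterparts and are varied only in the cancer-parameter screen; the healthy
# cohort screens vary the 37 structural parameters (stem, three lineages,
# macrophage block) while the chemotherapy protocol constants and the marrow
# capacity are held at their nominal values.

.roster_cache <- new.env(parent = emptyenv())

.param_roster <- function() {
  if (!is.null(.roster_cache$roster)) return(.roster_cache$roster)
  .roster_cache$roster <- tibble::tribble(
    ~name,     ~group,       ~fixed, ~scale,    ~unit,
    # stem-cell block
    "aS",      "stem",       FALSE,  "linear",  "1",
    "mrS",     "stem",       FALSE,  "log",     "1/day",
    "fN",      "stem",       FALSE,  "linear",  "1",
    "fL",      "stem",       FALSE,  "linear",  "1",
    "kS",      "stem",       FALSE,  "log",     "cells/uL",
    "kBM",     "stem",       FALSE,  "log",     "1",
    "dS",      "stem",       FALSE,  "log",     "1/day",
    # neutrophil lineage
    "aN2",     "neutrophil", FALSE,  "linear",  "1",
    "mrN2",    "neutrophil", FALSE,  "log",     "1/day",
    "sN2",     "neutrophil", FALSE,  "log",     "1/day",
    "kN",      "neutrophil", FALSE,  "log",     "cells/uL",
    "mbN",     "neutrophil", FALSE,  "log",     "1/day",
    "rN",      "neutrophil", FALSE,  "log",     "1/day",
    "mgN",     "neutrophil", FALSE,  "log",     "1/day",
    "dmN",     "neutrophil", FALSE,  "log",     "1/day",
    "kmovN",   "neutrophil", FALSE,  "log",     "cells/uL",
    # lymphocyte lineage (no marginal pool)
    "aL2",     "lymphocyte", FALSE,  "linear",  "1",
    "mrL2",    "lymphocyte", FALSE,  "log",     "1/day",
    "sL2",     "lymphocyte", FALSE,  "log",     "1/day",
    "kL",      "lymphocyte", FALSE,  "log",     "cells/uL",
    "mbL",     "lymphocyte", FALSE,  "log",     "1/day",
    "rL",      "lymphocyte", FALSE,  "log",     "1/day",
    "kmovL",   "lymphocyte", FALSE,  "log",     "cells/uL",
    # monocyte lineage
    "aM2",     "monocyte",   FALSE,  "linear",  "1",
    "mrM2",    "monocyte",   FALSE,  "log",     "1/day",
    "sM2",     "monocyte",   FALSE,  "log",     "1/day",
    "kM",      "monocyte",   FALSE,  "log",     "cells/uL",
    "mbM",     "monocyte",   FALSE,  "log",     "1/day",
    "rM",      "monocyte",   FALSE,  "log",     "1/day",
    "mgM",     "monocyte",   FALSE,  "log",     "1/day",
    "dmM",     "monocyte",   FALSE,  "log",     "1/day",
    "kmovM",   "monocyte",   FALSE,  "log",     "cells/uL",
    # macrophage / debris block
    "actMAC",  "macrophage", FALSE,  "log",     "1/day",
    "prMAC",   "macrophage", FALSE,  "log",     "1/day",
    "kA",      "macrophage", FALSE,  "log",     "cells/uL",
    "kMAC",    "macrophage", FALSE,  "log",     "cells/uL",
    "clA",     "macrophage", FALSE,  "log",     "1/day",
    # chemotherapy pharmacodynamics / pharmacokinetics
    "kkill",   "chemo",      FALSE,  "log",     "1/(drug unit * day)",
    "kel",     "chemo",      FALSE,  "log",     "1/day",
    # bone-marrow capacity
    "Kbm",     "capacity",   FALSE,  "log",     "cells/uL",
    # cancer block (defaults mirror monocytes)
    "dMc",     "cancer",     FALSE,  "log",     "1/day",
    "aMc2",    "cancer",     FALSE,  "linear",  "1",
    "mrMc2",   "cancer",     FALSE,  "log",     "1/day",
    "mbMc",    "cancer",     FALSE,  "log",     "1/day",
    # literature-fixed death rates
    "d2",      "death",      TRUE,   "log",     "1/day",
    "dN",      "death",      TRUE,   "log",     "1/day",
    "dL3",     "death",      TRUE,   "log",     "1/day",
    "dL3pb",   "death",      TRUE,   "log",     "1/day",
    "dM",      "death",      TRUE,   "log",     "1/day",
    "dMpb",    "death",      TRUE,   "log",     "1/day",
    "dMAC",    "death",      TRUE,   "log",     "1/day"
  )
  .roster_cache$roster
}

#' Parameter roster of the leukopoiesis model
#'
#' Returns one row per named model parameter (51 in total) with its lineage
#' group, whether it is fixed from literature (7 death rates) or uncertain /
#' sampled (44), its sampling scale (log for rates and Michaelis constants,
#' linear for probabilities and fractions), and its unit.
#'
#' @return A tibble with columns `name`, `group`, `fixed`, `scale`, `unit`.
#' @examples
#' leuko_parameters()
#' @export
leuko_parameters <- function() {
  .param_roster()
}

#' State names of the leukopoiesis model
#'
#' The 17 model states, in canonical order: hematopoietic stem cells (`S`);
#' neutrophil progenitors (`N2`), marrow (`Nbm`), circulating (`Npb`) and
#' marginal-pool (`Nmp`) neutrophils; lymphocyte progenitors (`L2`), maturing
#' tissue/thymus lymphocytes (`L3`) and circulating lymphocytes (`L3pb`);
#' monocyte progenitors (`M2`), marrow (`Mbm`), circulating (`Mpb`) and
#' marginal-pool (`Mmp`) monocytes; activated macrophages (`MAC`); apoptotic
#' debris (`A`); and the leukemic clone: cancer progenitors (`Mc2`), marrow
#' cancer (`Mcbm`) and circulating cancer (`Mcpb`). There is no lymphocyte
#' marginal pool.
#'
#' @return Character vector of length 17.
#' @export
leuko_states <- function() {
  c("S",
    "N2", "Nbm", "Npb", "Nmp",
    "L2", "L3", "L3pb",
    "M2", "Mbm", "Mpb", "Mmp",
    "MAC", "A",
    "Mc2", "Mcbm", "Mcpb")
}

# state index helpers
.circulating_pb_states <- function() c("Npb", "L3pb", "Mpb", "Mcpb")
.marginal_states <- function() c("Nmp", "Mmp")
# live bone-marrow / tissue occupancy (debris excluded: only live cells
# compete for marrow space and signal through the capacity feedback)
.bm_states <- function() c("S", "N2", "Nbm", "L2", "L3", "M2", "Mbm", "MAC", "Mc2", "Mcbm")
# states subject to chemotherapy by default (all but macrophages and debris)
.default_kill_states <- function() setdiff(leuko_states(), c("MAC", "A"))

#' Validate a named parameter vector
#'
#' Checks completeness against the roster and the structural constraints:
#' rates and Michaelis constants non-negative (constants strictly positive),
#' self-renewal probabilities in `[0, 1]` with healthy ones in `[0.5, 1]`
#' enforced at sampling time, and the stem lineage-split fractions `fN`,
#' `fL` (with `fM = 1 - fN - fL`) forming a proper partition.
#'
#' @param params Named numeric vector covering all 51 parameter names.
#' @return The parameter vector, invisibly, reordered canonically.
#' @export
validate_params <- function(params) {
  roster <- .param_roster()
  missing <- setdiff(roster$name, names(params))
  if (length(missing) > 0) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- params[roster$name]
  if (any(!is.finite(p))) {
    stop("non-finite parameter values", call. = FALSE)
  }
  frac <- c("aS", "aN2", "aL2", "aM2", "aMc2", "fN", "fL")
  if (any(p[frac] < 0) || any(p[frac] > 1)) {
    stop("probabilities and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (p[["fN"]] + p[["fL"]] > 1) {
    stop("lineage split fractions fN + fL must not exceed 1", call. = FALSE)
  }
  kconst <- c("kS", "kBM", "kN", "kmovN", "kL", "kmovL", "kM", "kmovM",
              "kA", "kMAC", "Kbm")
  if (any(p[kconst] <= 0)) {
    stop("Michaelis constants and capacity must be > 0", call. = FALSE)
  }
  rates <- setdiff(roster$name, c(frac, kconst))
  if (any(p[rates] < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' Tie the cancer block to a healthy reference lineage
#'
#' In healthy baseline simulations the leukemic clone carries the same rates
#' as the lineage it derives from: monocytic AML mirrors the monocyte block
#' (`dMc = dM`, `aMc2 = aM2`, `mrMc2 = mrM2`, `mbMc = mbM`), the neutrophilic
#' variant mirrors the neutrophil block. The cancer maturation rate is an
#' alias of the source lineage's maturation rate and is set in the solver
#' interface, not stored separately.
#'
#' @param params Named parameter vector.
#' @param source `"monocyte"` or `"neutrophil"`.
#' @return The parameter vector with the cancer block overwritten.
#' @export
mirror_cancer_params <- function(params, source = c("monocyte", "neutrophil")) {
  source <- match.arg(source)
  if (source == "monocyte") {
    params[c("dMc", "aMc2", "mrMc2", "mbMc")] <-
      params[c("dM", "aM2", "mrM2", "mbM")]
  } else {
    params[c("dMc", "aMc2", "mrMc2", "mbMc")] <-
      params[c("dN", "aN2", "mrN2", "mbN")]
  }
  params
}

# cancer maturation rate alias (sMc): maturation rate of the source lineage
.cancer_smc <- function(params, source = "monocyte") {
  if (identical(source, "neutrophil")) params[["sN2"]] else params[["sM2"]]
}
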