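## Extracellular enzyme C:N:P stoichiometry and vector analysis.
##
## Activities are in umol product g^-1 soil d^-1. The vector analysis maps
## the log activities of the C-acquiring enzyme (BG) and the N-acquiring
## enzymes (NAG + LAP) to a length (intensity of microbial carbon limitation)
## and an angle (nitrogen limitation below 45 degrees, phosphorus above).

check_activities <- function(...) {
  acts <- list(...)
  for (nm in names(acts)) {
    a <- acts[[nm]]
    if (any(!is.finite(a)) || any(a <= 0))
      abort("activity %s must be strictly positive and finite", nm)
  }
  invisible(TRUE)
}

#' Enzyme stoichiometric ratios
#'
#' Plain quotients of enzyme activities: `BG:(NAG+LAP)` (C- vs N-acquisition
#' investment), `NAG:LAP` (fungal vs bacterial N cycling; > 1 indicates
#' fungal dominance), `BG:ALP` (C- vs P-acquisition strategy) and `BG:PPO`
#' (labile vs recalcitrant C decomposition). All arguments are vectorised.
#'
#' @param BG,NAG,LAP,ALP,PPO strictly positive enzyme activities
#'   (umol d^-1 g^-1).
#' @return A data.frame with columns `ratio_cn` (BG:(NAG+LAP)), `ratio_nagl`
#'   (NAG:LAP), `ratio_cp` (BG:ALP), `ratio_cppo` (BG:PPO) and the logical
#'   `fungal_dominated` flag (`ratio_nagl > 1`).
#' @export
#' @examples
#' enzyme_ratios(BG = 62.74, NAG = 20.94, LAP = 10.50, ALP = 5.91, PPO = 32.17)
enzyme_ratios <- function(BG, NAG, LAP, ALP, PPO) {
  check_activities(BG = BG, NAG = NAG, LAP = LAP, ALP = ALP, PPO = PPO)
  data.frame(ratio_cn = BG / (NAG + LAP),
             ratio_nagl = NAG / LAP,
             ratio_cp = BG / ALP,
             ratio_cppo = BG / PPO,
             fungal_dominated = NAG / LAP > 1)
}

#' Enzyme vector length
#'
#' In the default `"literal"` mode the length is the Euclidean norm of the
#' two log activities, `sqrt(ln(BG)^2 + ln(NAG+LAP)^2)`; higher values
#' indicate stronger microbial carbon limitation. The interpretation assumes
#' both logarithms are positive (`BG > 1` and `NAG + LAP > 1`); activities at
#' or below 1 produce non-positive logs and the affected results are flagged
#' via the `"flagged"` attribute together with a warning, not silently
#' clipped. The `"relative"` mode is a sensitivity-analysis variant computed
#' on relative activity proportions `x = BG/(BG+ALP)`, `y = BG/(BG+NAG+LAP)`
#' with `L = sqrt(x^2 + y^2)`; it has no positivity-of-log requirement.
#'
#' @param BG,NAG,LAP strictly positive activities; vectorised.
#' @param ALP needed only for `mode = "relative"`.
#' @param mode `"literal"` (default) or `"relative"`.
#' @return Numeric vector of lengths with a logical `"flagged"` attribute.
#' @export
vector_length <- function(BG, NAG, LAP, ALP = NULL, mode = c("literal", "relative")) {
  mode <- match.arg(mode)
  check_activities(BG = BG, NAG = NAG, LAP = LAP)
  if (mode == "relative") {
    if (is.null(ALP)) abort("relative mode requires ALP")
    check_activities(ALP = ALP)
    x <- BG / (BG + ALP)
    y <- BG / (BG + NAG + LAP)
    out <- sqrt(x^2 + y^2)
    attr(out, "flagged") <- rep(FALSE, length(out))
    return(out)
  }
  lb <- log(BG)
  ln <- log(NAG + LAP)
  flagged <- lb < 0 | ln < 0
  if (any(flagged))
    warning("activity <= 1 gives a non-positive log; affected samples flagged",
            call. = FALSE)
  out <- sqrt(lb^2 + ln^2)
  attr(out, "flagged") <- flagged
  out
}

#' Enzyme vector angle (degrees)
#'
#' In `"literal"` mode the angle is `atan(ln(NAG+LAP) / ln(BG))` converted to
#' degrees, with the limit convention that `ln(BG) = 0` with
#' `ln(NAG+LAP) > 0` gives 90 degrees. Angles below 45 degrees indicate
#' nitrogen limitation, above 45 phosphorus limitation. Samples with a
#' non-positive log are flagged as in [vector_length()] (the angle then loses
#' its interpretation). In `"relative"` mode the angle is
#' `atan2(x, y)` in degrees on the proportions defined in [vector_length()].
#'
#' @inheritParams vector_length
#' @return Numeric vector of angles in degrees with a `"flagged"` attribute.
#' @export
vector_angle <- function(BG, NAG, LAP, ALP = NULL, mode = c("literal", "relative")) {
  mode <- match.arg(mode)
  check_activities(BG = BG, NAG = NAG, LAP = LAP)
  if (mode == "relative") {
    if (is.null(ALP)) abort("relative mode requires ALP")
    check_activities(ALP = ALP)
    x <- BG / (BG + ALP)
    y <- BG / (BG + NAG + LAP)
    out <- atan2(x, y) * 180 / pi
    attr(out, "flagged") <- rep(FALSE, length(out))
    return(out)
  }
  lb <- log(BG)
  ln <- log(NAG + LAP)
  flagged <- lb < 0 | ln < 0
  if (any(flagged))
    warning("activity <= 1 gives a non-positive log; affected samples flagged",
            call. = FALSE)
  out <- ifelse(lb == 0,
                ifelse(ln > 0, 90, 0),
                atan(ln / lb) * 180 / pi)
  attr(out, "flagged") <- flagged
  out
}

#' Classify nutrient limitation from a vector angle
#'
#' Nitrogen limitation below 45 degrees, phosphorus limitation above, and
#' `"balanced"` at exactly 45 degrees. Classification is refused (error) for
#' angles flagged as uninterpretable by [vector_angle()] unless the flag is
#' dropped by the caller.
#'
#' @param angle numeric angles in degrees, typically from [vector_angle()].
#' @return Character vector in `{"nitrogen", "phosphorus", "balanced"}`.
#' @export
classify_limitation <- function(angle) {
  flagged <- attr(angle, "flagged")
  if (!is.null(flagged) && any(flagged))
    abort("cannot classify: %d angle(s) flagged as uninterpretable", sum(flagged))
  if (any(!is.finite(angle))) abort("non-finite angle")
  ifelse(angle < 45, "nitrogen", ifelse(angle > 45, "phosphorus", "balanced"))
}

#' Per-sample enzyme stoichiometry table
#'
#' Convenience wrapper applying [enzyme_ratios()], [vector_length()],
#' [vector_angle()] and [classify_limitation()] to every row of a sample
#' table holding the five enzyme activity columns.
#'
#' @param table data.frame with numeric columns `BG`, `NAG`, `LAP`, `ALP`,
#'   `PPO` (other columns, e.g. `treatment`, are carried through).
#' @param mode passed to the vector functions.
#' @return A data.frame: the carried-through identifier columns plus all four
#'   ratios, `vector_l`, `vector_a`, `limitation` and `c_limitation_score`
#'   (equal to the vector length). Flagged samples get `NA` limitation.
#' @export
stoichiometry <- function(table, mode = c("literal", "relative")) {
  mode <- match.arg(mode)
  need <- c("BG", "NAG", "LAP", "ALP", "PPO")
  if (!all(need %in% names(table)))
    abort("table must contain columns %s", paste(need, collapse = ", "))
  keep <- intersect(c("treatment", "replicate", "sample"), names(table))
  out <- table[, keep, drop = FALSE]
  out <- cbind(out, enzyme_ratios(table$BG, table$NAG, table$LAP,
                                  table$ALP, table$PPO))
  L <- vector_length(table$BG, table$NAG, table$LAP, table$ALP, mode = mode)
  A <- vector_angle(table$BG, table$NAG, table$LAP, table$ALP, mode = mode)
  flagged <- attr(A, "flagged")
  out$vector_l <- as.numeric(L)
  out$vector_a <- as.numeric(A)
  out$limitation <- NA_character_
  ok <- !flagged
  if (any(ok))
    out$limitation[ok] <- classify_limitation(as.numeric(A)[ok])
  out$flagged <- flagged
  out$c_limitation_score <- as.numeric(L)
  out
}
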