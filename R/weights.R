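# SNP weights for the relationship matrix. Weights are relative: a weight
# vector over N loci always sums to N (mean weight 1), so the unweighted
# matrix corresponds to all-ones.

#' FST-proportional relative weights
#'
#' Converts per-locus scores into relative weights
#' `w_i = fst_i / sum_j(fst_j) * N`, which sum to `N` (the number of loci) so
#' the average weight is 1. Zero-score loci get weight 0.
#'
#' @param fst Numeric vector of nonnegative per-locus scores, optionally
#'   named by locus.
#' @return Named numeric weight vector of the same length.
#' @examples
#' fst_weights(c(a = 0.2, b = 0.6))  # 0.5, 1.5
#' @export
fst_weights <- function(fst) {
  if (any(fst < 0)) stop("scores must be nonnegative", call. = FALSE)
  s <- sum(fst)
  if (s <= 0)
    stop("all scores are zero: proportional weights are undefined",
         call. = FALSE)
  fst / s * length(fst)
}

#' Define a SNP weighting scenario
#'
#' A scenario distributes the total relative weight between the prioritized
#' top-k SNP group and the remaining SNPs. Percentage scenarios such as
#' `"90:10"` assign 90% of the total weight budget to the top group and 10%
#' to the rest, spread within each group by `within` (`"equal"`, the default,
#' or `"fst"` for score-proportional within-group weights). Two special
#' full-panel scenarios exist: `"ps"` (every SNP weighted proportionally to
#' its score) and `"equal"` (all weights 1, the unweighted matrix). The
#' top-only panel variants `"top-equal"` and `"top-fst"` restrict the panel
#' to the prioritized SNPs with equal or score-proportional weights.
#'
#' @param name Scenario string: `"<top>:<rest>"` percentages (e.g.
#'   `"100:0"`, `"25:75"`), `"ps"`, `"equal"`, `"top-equal"` or `"top-fst"`.
#' @param within Within-group distribution rule for percentage scenarios.
#' @return An object of class `"weighting_scenario"`: `name`, `panel`
#'   (`"full"` or `"top"`), `top_share`, `rest_share` (percent) and `within`.
#' @export
weighting_scenario <- function(name, within = c("equal", "fst")) {
  within <- match.arg(within)
  name <- tolower(name)
  if (name == "ps") {
    sc <- list(name = "ps", panel = "full", top_share = NA_real_,
               rest_share = NA_real_, within = "fst")
  } else if (name == "equal") {
    sc <- list(name = "equal", panel = "full", top_share = NA_real_,
               rest_share = NA_real_, within = "equal")
  } else if (name == "top-equal") {
    sc <- list(name = "top-equal", panel = "top", top_share = 100,
               rest_share = 0, within = "equal")
  } else if (name == "top-fst") {
    sc <- list(name = "top-fst", panel = "top", top_share = 100,
               rest_share = 0, within = "fst")
  } else if (grepl("^[0-9.]+:[0-9.]+$", name)) {
    shares <- as.numeric(strsplit(name, ":")[[1L]])
    if (any(shares < 0) || abs(sum(shares) - 100) > 1e-9)
      stop("scenario shares must be nonnegative and sum to 100", call. = FALSE)
    sc <- list(name = name, panel = "full", top_share = shares[1L],
               rest_share = shares[2L], within = within)
  } else stop("unrecognized scenario: ", name, call. = FALSE)
  class(sc) <- "weighting_scenario"
  sc
}

#' @export
print.weighting_scenario <- function(x, ...) {
  cat(sprintf("Weighting scenario '%s': panel = %s", x$name, x$panel))
  if (!is.na(x$top_share))
    cat(sprintf(", budget %g%% top / %g%% rest", x$top_share, x$rest_share))
  cat(sprintf(", within-group = %s\n", x$within))
  invisible(x)
}

#' The scenario set of the weighting study
#'
#' Seven full-panel scenarios — budgets (100,0), (90,10), (75,25), (50,50),
#' (25,75) for the prioritized/remaining groups, score-proportional (`ps`)
#' and unweighted (`equal`) — plus the two top-only panel variants.
#'
#' @return Named list of [weighting_scenario()] objects.
#' @export
default_scenarios <- function() {
  names <- c("100:0", "90:10", "75:25", "50:50", "25:75", "ps", "equal",
             "top-equal", "top-fst")
  stats::setNames(lapply(names, weighting_scenario), names)
}

#' Realize a weighting scenario as a per-locus weight vector
#'
#' For full-panel percentage scenarios the total weight `N` (panel size) is
#' split so that the prioritized group carries `top_share` percent and the
#' remainder `rest_share` percent, distributed within each group either
#' equally or proportionally to the FST scores. `ps` applies
#' [fst_weights()] to the whole panel and `equal` returns all ones. Top-only
#' scenarios return weights over the prioritized loci alone.
#'
#' @param scores An `"fst_scores"` data frame (see [fst_scores()]), or a
#'   named numeric vector of scores.
#' @param top_loci Character vector of prioritized locus ids (from
#'   [fst_top_k()]).
#' @param scenario A [weighting_scenario()] or a scenario name string.
#' @return Named weight vector over the scenario's panel (full panel or top
#'   group); nonnegative, summing to the panel size.
#' @export
scenario_weights <- function(scores, top_loci, scenario) {
  if (is.character(scenario)) scenario <- weighting_scenario(scenario)
  stopifnot(inherits(scenario, "weighting_scenario"))
  if (is.data.frame(scores)) {
    fst <- stats::setNames(scores$fst, scores$locus)
  } else {
    fst <- scores
    if (is.null(names(fst))) names(fst) <- as.character(seq_along(fst))
  }
  if (length(top_loci) == 0L) stop("empty top locus set", call. = FALSE)
  if (!all(top_loci %in% names(fst)))
    stop("some top loci are not in the score set", call. = FALSE)
  in_top <- names(fst) %in% top_loci

  if (scenario$panel == "top") {
    fst_top <- fst[in_top]
    w <- if (scenario$within == "equal") rep(1, length(fst_top))
         else fst_weights(fst_top)
    return(stats::setNames(as.numeric(w), names(fst_top)))
  }
  N <- length(fst)
  if (scenario$name == "equal") return(stats::setNames(rep(1, N), names(fst)))
  if (scenario$name == "ps") return(fst_weights(fst))
  k <- sum(in_top)
  w <- numeric(N)
  budget_top <- scenario$top_share / 100 * N
  budget_rest <- scenario$rest_share / 100 * N
  spread <- function(idx, budget) {
    if (!any(idx) || budget == 0) return(numeric(sum(idx)))
    if (scenario$within == "equal") rep(budget / sum(idx), sum(idx))
    else {
      s <- sum(fst[idx])
      if (s <= 0) stop("all scores in a weighted group are zero", call. = FALSE)
      budget * fst[idx] / s
    }
  }
  w[in_top] <- spread(in_top, budget_top)
  w[!in_top] <- spread(!in_top, budget_rest)
  stats::setNames(w, names(fst))
}
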