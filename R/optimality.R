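#' Signed pseudo-logarithmic normalization to [0, 1]
#'
#' Applies the signed pseudo-logarithm `asinh(z/2)/ln(10)` — a log-like
#' transform that is defined at zero and preserves sign — and then min-max
#' rescales to `[0, 1]`. Constant input maps to all zeros. Any positive
#' multiplicative constant in front of the `asinh` is annihilated by the
#' rescaling, so only the signed, unsquared form is observable.
#'
#' @param values numeric vector (finite).
#' @return numeric vector in `[0, 1]`.
#' @export
#' @examples
#' pseudo_log_normalize(c(-3, 0, 3))  # 0, 0.5, 1
pseudo_log_normalize <- function(values) {
  if (!length(values)) stop("empty input")
  if (any(!is.finite(values))) stop("non-finite values in input")
  t <- asinh(values / 2) / log(10)
  rng <- range(t)
  if (rng[2] == rng[1]) return(rep(0, length(values)))
  (t - rng[1]) / (rng[2] - rng[1])
}

#' Absolute Optimality
#'
#' The AO of a reaction is the L2 norm of its normalized flux and normalized
#' sensitivity: `AO_i = sqrt(N(v_i)^2 + N(delta_i)^2)`, ranging over
#' `[0, sqrt(2)]`. Reactions that both carry flux and constrain the optimum
#' score high.
#'
#' @param n_flux,n_sens numeric vectors in `[0, 1]`, equal length.
#' @return numeric AO vector.
#' @export
absolute_optimality <- function(n_flux, n_sens) {
  if (length(n_flux) != length(n_sens)) {
    stop("n_flux and n_sens must have equal length")
  }
  stopifnot(all(n_flux >= 0 & n_flux <= 1), all(n_sens >= 0 & n_sens <= 1))
  sqrt(n_flux^2 + n_sens^2)
}

#' Per-cell top-percentile selection
#'
#' Within each cell label separately, computes the empirical q-th percentile
#' of the scores (linear interpolation between closest ranks) and returns the
#' ids whose score is greater than or equal to that cutoff. Exchange-labeled
#' items are pooled into both cellular strata (an exchange reaction borders
#' the extracellular space shared by both cells); they are reported at most
#' once.
#'
#' @param scores numeric vector.
#' @param cell_labels character vector (`"neuron"`, `"astrocyte"`,
#'   `"exchange"`), same length as `scores`.
#' @param ids identifiers to return; defaults to `names(scores)`.
#' @param q percentile in (0, 100]; default 90. `q = 0` selects everything.
#' @return character vector of selected ids.
#' @export
select_top_percentile <- function(scores, cell_labels, ids = names(scores),
                                  q = 90) {
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  stopifnot(length(scores) == length(cell_labels),
            length(scores) == length(ids), q >= 0, q <= 100)
  if (any(!is.finite(scores))) stop("non-finite scores")
  selected <- character(0)
  for (cell in c("neuron", "astrocyte")) {
    in_stratum <- cell_labels == cell | cell_labels == "exchange"
    if (!any(cell_labels == cell)) {
      warning("empty stratum skipped: ", cell)
      next
    }
    cutoff <- stats::quantile(scores[in_stratum], q / 100, type = 7,
                              names = FALSE)
    selected <- c(selected, ids[in_stratum & scores >= cutoff])
  }
  unique(selected)
}

#' Wilcoxon rank-sum comparison of two cellular strata
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test comparing the neuron and
#' astrocyte score distributions.
#'
#' @param values numeric vector of scores.
#' @param cell_labels character labels; only `"neuron"` and `"astrocyte"`
#'   entries enter the test.
#' @return list with `statistic` (rank-sum W) and `p_value`.
#' @export
rank_sum_compare <- function(values, cell_labels) {
  x <- values[cell_labels == "neuron"]
  y <- values[cell_labels == "astrocyte"]
  if (!length(x) || !length(y)) {
    stop("both neuron and astrocyte strata must be non-empty")
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Build the Absolute Optimality table of an FBA solution
#'
#' Normalizes fluxes and reduced costs over the whole network with
#' [pseudo_log_normalize()], combines them into AO and flags the per-cell
#' top-`q` percentile as optimal reactions.
#'
#' @param model a [metabolic_model()].
#' @param solution an optimal [solve_fba()] result.
#' @param q percentile cutoff (default 90).
#' @param abs_before_norm normalize absolute values instead of signed values.
#' @param per_cell normalize within each cell label instead of network-wide.
#' @return data.frame with columns `reaction_id`, `cell_label`, `flux`,
#'   `sensitivity`, `n_flux`, `n_sens`, `ao`, `is_optimal`.
#' @export
optimality_table <- function(model, solution, q = 90,
                             abs_before_norm = FALSE, per_cell = FALSE) {
  if (!identical(solution$status, "optimal")) {
    stop("optimality table requires an optimal solution")
  }
  v <- as.numeric(solution$v); d <- as.numeric(solution$delta)
  if (abs_before_norm) { v <- abs(v); d <- abs(d) }
  norm_one <- function(x) pseudo_log_normalize(x)
  if (per_cell) {
    n_flux <- n_sens <- numeric(length(v))
    for (cell in unique(model$cell_label)) {
      i <- model$cell_label == cell
      n_flux[i] <- norm_one(v[i]); n_sens[i] <- norm_one(d[i])
    }
  } else {
    n_flux <- norm_one(v); n_sens <- norm_one(d)
  }
  ao <- absolute_optimality(n_flux, n_sens)
  sel <- select_top_percentile(ao, model$cell_label, model$reaction_ids, q)
  data.frame(reaction_id = model$reaction_ids,
             cell_label = model$cell_label,
             flux = as.numeric(solution$v),
             sensitivity = as.numeric(solution$delta),
             n_flux = n_flux, n_sens = n_sens, ao = ao,
             is_optimal = model$reaction_ids %in% sel,
             stringsAsFactors = FALSE)
}
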