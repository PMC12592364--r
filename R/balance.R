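#' Iterative-correction (ICE) balancing
#'
#' Computes per-bin weights `w` so that the corrected matrix
#' `c'_ij = c_ij * w_i * w_j` has (approximately) equal marginals over
#' non-masked bins. Each update divides the weights by the current corrected
#' marginal and renormalizes them to mean 1 per chromosome, so a single
#' iteration from flat weights gives `w_i` proportional to `1/marginal_i`.
#' The default is that single pass; `tol` switches to convergence mode,
#' iterating until the coefficient of variation of the corrected marginals
#' drops below `tol`.
#'
#' Bins whose raw marginal is zero are masked before correction. Balancing is
#' per chromosome, in cis.
#'
#' @param map A [contact_map()] of raw counts (mask already applied).
#' @param n_iter Number of update iterations (default 1).
#' @param tol If non-`NULL`, iterate until the marginal coefficient of
#'   variation is `< tol` (up to `max_iter`), ignoring `n_iter`.
#' @param max_iter Iteration cap in `tol` mode.
#' @return The map with `weights` filled in; masked bins have `NA` weight.
#' @export
ice_normalize <- function(map, n_iter = 1, tol = NULL, max_iter = 2000) {
  check_that(map$unit == "counts", "can only balance a counts map")
  check_that(is.null(tol) || (is_scalar_number(tol) && tol > 0),
             "`tol` must be a positive number")
  check_that(is_count(n_iter) && n_iter >= 1, "`n_iter` must be >= 1")
  idx <- cm_index(map)
  weights <- rep(NA_real_, nrow(map$bins))
  for (ch in names(map$matrices)) {
    m <- map$matrices[[ch]]
    gi <- idx[[ch]]
    active <- !map$mask[gi] & rowSums(m) > 0
    map$mask[gi[!active & !map$mask[gi]]] <- TRUE
    if (!any(active)) next
    w <- ifelse(active, 1, NA_real_)
    wz <- ifelse(active, 1, 0)
    iters <- if (is.null(tol)) n_iter else max_iter
    for (it in seq_len(iters)) {
      marg <- as.vector(m %*% wz) * wz
      if (!is.null(tol) && cv(marg[active]) < tol) break
      w[active] <- w[active] / marg[active]
      w[active] <- w[active] / mean(w[active])
      wz <- ifelse(active, w, 0)
    }
    weights[gi] <- w
  }
  check_that(!all(map$mask), "all bins are masked; nothing to balance")
  map$weights <- weights
  map
}

#' Coefficient of variation of corrected marginals
#'
#' Convergence diagnostic for [ice_normalize()]: per chromosome, the CV of
#' the balanced-matrix marginals over non-masked bins.
#'
#' @param map A balanced [contact_map()].
#' @return Named numeric vector, one CV per chromosome.
#' @export
marginal_cv <- function(map) {
  check_that(!is.null(map$weights), "map is not balanced")
  idx <- cm_index(map)
  vapply(names(map$matrices), function(ch) {
    b <- balanced_matrix(map, ch)
    ok <- !map$mask[idx[[ch]]] & !is.na(map$weights[idx[[ch]]])
    if (sum(ok) < 2) return(NA_real_)
    cv(rowSums(b[ok, ok, drop = FALSE]))
  }, numeric(1))
}
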