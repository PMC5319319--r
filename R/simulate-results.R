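#' Simulate a results table with known effects
#'
#' Generates a long-format trial table directly from a linear mixed model --
#' no flock simulation involved -- for power checks, null simulations and
#' parameter-recovery tests of the analysis pipeline. For each response the
#' generating model is
#'
#'   y = b0 + b_size * ln(N) + b_size2 * ln(N)^2 + b_dens * density
#'       + b_int * ln(N) * density + u_participant + e,
#'
#' with u ~ N(0, sd_participant^2) and e ~ N(0, sd_resid^2).
#'
#' @param participants Number of participants.
#' @param reps Trials per size x density cell per participant.
#' @param sizes,densities Design levels (densities as numeric NND, m).
#' @param effects Named list of coefficient lists, one per generated
#'   response column; each may set `b0`, `b_size`, `b_size2`, `b_dens`,
#'   `b_int`, `sd_participant`, `sd_resid` (missing entries are 0, except
#'   `sd_resid` which defaults to 1).
#' @param seed Integer seed.
#' @return A `results_table` data.frame with columns participant, phase,
#'   flock_size, density, timed_out and one column per entry of `effects`.
#' @export
simulate_results_table <- function(participants = 10L, reps = 5L,
                                   sizes = c(1, 50, 250, 1000, 5000),
                                   densities = c(0.8, 1.3, 1.8),
                                   effects = list(
                                     targeting_error_m = list(
                                       b0 = 2, sd_participant = 0.5,
                                       sd_resid = 1)),
                                   seed = 1L) {
  set.seed(as.integer(seed))
  cells <- expand.grid(flock_size = sizes, density = densities)
  tab <- do.call(rbind, lapply(seq_len(participants), function(p) {
    d <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
    d$participant <- p
    d
  }))
  tab$phase <- "experimental"
  tab$timed_out <- FALSE
  ls <- log(tab$flock_size)
  for (resp in names(effects)) {
    ef <- effects[[resp]]
    g <- function(nm, default = 0) ef[[nm]] %||% default
    u <- stats::rnorm(participants, 0, g("sd_participant"))
    tab[[resp]] <- g("b0") + g("b_size") * ls + g("b_size2") * ls^2 +
      g("b_dens") * tab$density + g("b_int") * ls * tab$density +
      u[tab$participant] +
      stats::rnorm(nrow(tab), 0, g("sd_resid", 1))
  }
  rownames(tab) <- NULL
  class(tab) <- c("results_table", class(tab))
  tab
}
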