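#' Simulate Tn5 insertion tracks around motif sites
#'
#' Emits per-site, per-position insertion counts over a window centered
#' on a motif, together with the position-level Tn5 sequence-bias track
#' used to generate them. Counts at position `p` of site `s` are
#' `Poisson(rate * bias_p * d_p)` where `d_p = 1 - depletion` inside the
#' motif core (a bound factor shields the core from transposition) and 1
#' elsewhere. The bias track is a smoothed lognormal profile standing in
#' for k-mer composition effects and is reported so downstream
#' correction can subtract it.
#'
#' @param config a [sim_config()] object (`footprint_depletion`, `seed`).
#' @param n_sites number of motif occurrences aggregated.
#' @param flank half-window in bp on each side of the motif center.
#' @param motif_len motif core length in bp.
#' @param rate expected insertions per position per site before bias.
#' @param depletion override of `config$footprint_depletion`.
#' @param stream RNG child-stream suffix.
#' @return list of class `footprint_track`: `counts` (sites x positions),
#'   `bias` (length 2*flank+1), `positions` (bp relative to motif
#'   center), `core` (logical mask of core positions), `motif_len`.
#' @examples
#' tr <- simulate_footprint_track(sim_config(seed = 2), n_sites = 20)
#' dim(tr$counts)
#' @export
simulate_footprint_track <- function(config, n_sites = 200, flank = 250,
                                     motif_len = 10, rate = 0.5,
                                     depletion = NULL, stream = "") {
  stopifnot(inherits(config, "sim_config"))
  if (2 * flank + 1 <= motif_len) stop("window must exceed the motif length")
  if (is.null(depletion)) depletion <- config$footprint_depletion
  if (depletion < 0 || depletion > 1) stop("depletion must lie in [0, 1]")
  with_seed(child_seed(config$seed, paste0("footprint", stream)), {
    npos <- 2L * flank + 1L
    positions <- seq(-flank, flank)
    # lognormal bias smoothed over a 5-bp window, mean-one
    raw <- exp(rnorm(npos, 0, 0.4))
    kern <- rep(1 / 5, 5)
    bias <- as.vector(stats::filter(raw, kern, sides = 2))
    bias[is.na(bias)] <- raw[is.na(bias)]
    bias <- bias / mean(bias)
    half <- motif_len %/% 2L
    core <- abs(positions) <= half
    dep <- ifelse(core, 1 - depletion, 1)
    mu <- rate * bias * dep
    counts <- matrix(rpois(n_sites * npos, rep(mu, each = n_sites)),
                     n_sites, npos)
    colnames(counts) <- positions
    structure(list(counts = counts, bias = bias, positions = positions,
                   core = core, motif_len = motif_len),
              class = "footprint_track")
  })
}
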