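# Interaction-entropy estimator: the entropic contribution to binding,
# -TdS = KT ln< exp(beta * dE_int) >, computed from the fluctuations
# dE_int = E_int - <E_int> of the inter-partner interaction energy along a
# trajectory. The exponential average is evaluated in max-shifted log-sum-exp
# form: exp(beta * dE) overflows doubles once fluctuations reach a few hundred
# KT, which real interface energy series do in their tails.

# Core estimator on a bare numeric vector. Returns KT * log mean exp(beta*dE),
# which is >= 0 by Jensen's inequality (0 iff the series is constant).
.ie_estimate <- function(values, temperature) {
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (!all(is.finite(values))) stop("series contains non-finite values")
  n <- length(values)
  if (n < 2L) return(0)
  kt <- .kB * temperature
  z <- (values - mean(values)) / kt      # beta * dE
  m <- max(z)
  v <- kt * (m + log(mean(exp(z - m))))
  # mathematically >= 0; guard the last-bit rounding case
  if (v < 0 && v > -1e-9) v <- 0
  v
}

#' Interaction entropy from an interaction-energy series
#'
#' Estimates the entropic contribution -TdS (kcal/mol, non-negative) to the
#' gas-phase binding free energy from the fluctuations of the inter-partner
#' interaction energy:
#' `-TdS = KT * ln( (1/N) * sum_i exp(beta * (E_i - mean(E))) )`,
#' with `beta = 1/KT`. Every stored snapshot contributes; no fitting or mode
#' analysis is involved.
#'
#' @param series An [energy_series()] (typically the `total` inter-partner
#'   interaction series), or a bare numeric vector.
#' @param temperature Temperature in K; defaults to the series' own.
#' @param trace_stride Stride for the stored convergence trace (frames between
#'   trace points); `NULL` picks about 100 points.
#' @param n_blocks Number of contiguous blocks for the block-wise uncertainty;
#'   `block_std` is `NA` when the series is shorter than `2 * n_blocks`.
#' @return An object of class `"ie_result"`: list with `mean_interaction`,
#'   `minus_t_delta_s`, `temperature`, `n_frames`, `beta`,
#'   `convergence_trace` (data.frame `frame`, `minus_t_delta_s`) and
#'   `block_std`.
#' @examples
#' s <- energy_series(c(-10, -12), temperature = 300)
#' interaction_entropy(s)$minus_t_delta_s  # KT * ln cosh(beta) ~ 0.607
#' @export
interaction_entropy <- function(series, temperature = NULL,
                                trace_stride = NULL, n_blocks = 10) {
  values <- if (inherits(series, "energy_series")) series$values
            else as.numeric(series)
  if (is.null(temperature))
    temperature <- if (inherits(series, "energy_series")) series$temperature
                   else .default_temperature
  n <- length(values)
  if (n < 1L) stop("series must contain at least one value")
  mts <- .ie_estimate(values, temperature)
  if (is.null(trace_stride)) trace_stride <- max(1L, n %/% 100L)
  trace <- if (n >= 2L) {
    .ie_prefix_trace(values, temperature, trace_stride)
  } else data.frame(frame = n, minus_t_delta_s = 0)
  # the final trace point is the full-series estimate by construction
  block_std <- if (n >= 2L * n_blocks)
    block_uncertainty(values, temperature, n_blocks = n_blocks) else NA_real_
  structure(list(mean_interaction = mean(values),
                 minus_t_delta_s = mts,
                 temperature = temperature,
                 n_frames = n,
                 beta = 1 / (.kB * temperature),
                 convergence_trace = trace,
                 block_std = block_std),
            class = "ie_result")
}

#' @export
print.ie_result <- function(x, ...) {
  cat(sprintf("interaction entropy over %d frames at %g K\n",
              x$n_frames, x$temperature))
  cat(sprintf("  <E_int> = %.2f kcal/mol\n", x$mean_interaction))
  cat(sprintf("  -TdS    = %.2f kcal/mol%s\n", x$minus_t_delta_s,
              if (is.na(x$block_std)) ""
              else sprintf(" (block std %.2f)", x$block_std)))
  invisible(x)
}

# prefix trace at frames stride, 2*stride, ..., n (n always included); each
# point is a standalone estimate on the prefix, mean re-centred per prefix.
.ie_prefix_trace <- function(values, temperature, stride) {
  n <- length(values)
  pts <- unique(c(seq(stride, n, by = stride), n))
  pts <- pts[pts >= 2L]
  if (!length(pts)) pts <- n
  mts <- vapply(pts, function(k) .ie_estimate(values[seq_len(k)], temperature),
                numeric(1))
  data.frame(frame = pts, minus_t_delta_s = mts)
}

#' Convergence trace of the interaction-entropy estimate
#'
#' Point k of the trace is the -TdS estimate computed on exactly the first
#' `k * stride` frames, with the fluctuation mean re-centred on that prefix,
#' so every point is a valid standalone estimate. The final point (always
#' included) equals the full-series estimate bit-for-bit.
#'
#' @param series An [energy_series()] or numeric vector.
#' @param temperature Temperature in K.
#' @param stride Frames between trace points (>= 1, <= series length).
#' @return A data.frame with columns `frame`, `time_fs`, `minus_t_delta_s`.
#' @export
convergence_trace <- function(series, temperature = NULL, stride = 1) {
  values <- if (inherits(series, "energy_series")) series$values
            else as.numeric(series)
  fi <- if (inherits(series, "energy_series")) series$frame_interval else 1
  if (is.null(temperature))
    temperature <- if (inherits(series, "energy_series")) series$temperature
                   else .default_temperature
  if (stride < 1) stop("stride must be >= 1")
  if (stride > length(values))
    stop("stride (", stride, ") exceeds series length (", length(values), ")")
  tr <- .ie_prefix_trace(values, temperature, as.integer(stride))
  data.frame(frame = tr$frame, time_fs = (tr$frame - 1) * fi,
             minus_t_delta_s = tr$minus_t_delta_s)
}

#' Per-residue interaction entropy
#'
#' Applies [interaction_entropy()] independently to each residue's total
#' (ele + vdw) interaction series, as produced by
#' [per_residue_interaction_series()]. Because the estimator is a nonlinear
#' functional, the per-residue values do not sum to the whole-system -TdS;
#' they are reported without rescaling.
#'
#' @param res_series Named list keyed by residue, each element either a list
#'   with a `total` [energy_series()] (the output shape of
#'   [per_residue_interaction_series()]) or a single series/numeric vector.
#' @param temperature Temperature in K.
#' @return Named numeric vector of -TdS per residue (kcal/mol).
#' @export
per_residue_entropy <- function(res_series, temperature = NULL) {
  vals <- lapply(res_series, function(r) {
    v <- if (is.list(r) && !inherits(r, "energy_series")) r$total else r
    if (inherits(v, "energy_series")) v$values else as.numeric(v)
  })
  lens <- vapply(vals, length, integer(1))
  if (length(unique(lens)) > 1L)
    stop("residue series have mismatched lengths: ",
         paste(range(lens), collapse = " vs "))
  if (is.null(temperature)) {
    first <- res_series[[1]]
    v <- if (is.list(first) && !inherits(first, "energy_series")) first$total
         else first
    temperature <- if (inherits(v, "energy_series")) v$temperature
                   else .default_temperature
  }
  vapply(vals, .ie_estimate, numeric(1), temperature = temperature)
}

#' Block-wise uncertainty of the interaction-entropy estimate
#'
#' Splits the series into `n_blocks` equal contiguous blocks (truncating the
#' remainder), computes the chosen statistic per block, and returns the sample
#' standard deviation (denominator n-1) across blocks.
#'
#' @param series An [energy_series()] or numeric vector.
#' @param temperature Temperature in K (used by the `"ie"` statistic).
#' @param n_blocks Number of blocks (>= 2); series length must be at least
#'   `2 * n_blocks`.
#' @param statistic `"ie"` (per-block -TdS) or `"mean"` (per-block mean).
#' @return Standard deviation across blocks, kcal/mol.
#' @export
block_uncertainty <- function(series, temperature = NULL, n_blocks = 10,
                              statistic = c("ie", "mean")) {
  statistic <- match.arg(statistic)
  values <- if (inherits(series, "energy_series")) series$values
            else as.numeric(series)
  if (is.null(temperature))
    temperature <- if (inherits(series, "energy_series")) series$temperature
                   else .default_temperature
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  n <- length(values)
  if (n < 2L * n_blocks)
    stop("series too short (", n, ") for ", n_blocks, " blocks")
  block_len <- n %/% n_blocks
  per_block <- vapply(seq_len(n_blocks), function(b) {
    x <- values[((b - 1L) * block_len + 1L):(b * block_len)]
    if (statistic == "ie") .ie_estimate(x, temperature) else mean(x)
  }, numeric(1))
  stats::sd(per_block)
}
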