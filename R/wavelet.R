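#' @include AllClasses.R
NULL

# Least-asymmetric (symlet) order-4 scaling filter, standard published
# coefficients (L = 8, unit energy, sum = sqrt(2)).
SYM4_SCALING <- c(0.0322231006040427, -0.012603967262037833,
                  -0.09921954357684722, 0.29785779560527736,
                  0.8037387518059161, 0.49761866763201545,
                  -0.02963552764599851, -0.07576571478927333)

# Quadrature-mirror wavelet filter: h_l = (-1)^l g_{L-1-l}.
qmf <- function(g) {
  L <- length(g)
  (-1)^(0:(L - 1)) * rev(g)
}

# Circular filtering with an upsampled filter: y[t] = sum_l c[l] *
# x[(t - s*l) mod N] (analysis) or x[(t + s*l) mod N] (synthesis).
circFilt <- function(x, coefs, s, synthesis = FALSE) {
  n <- length(x)
  y <- numeric(n)
  idx0 <- seq_len(n) - 1L
  sgn <- if (synthesis) 1L else -1L
  for (l in seq_along(coefs)) {
    shift <- (l - 1L) * s * sgn
    y <- y + coefs[l] * x[((idx0 + shift) %% n) + 1L]
  }
  y
}

#' Maximal-overlap discrete wavelet transform (MODWT)
#'
#' Non-decimated, shift-invariant wavelet decomposition using circular
#' boundary treatment. With the rescaled filters
#' \eqn{\tilde g = g/\sqrt 2}, \eqn{\tilde h = h/\sqrt 2}, level-j
#' coefficients are produced by filtering the level-(j-1) scaling
#' coefficients with the filters upsampled by \eqn{2^{j-1}}.
#'
#' @param x numeric series.
#' @param nLevels decomposition depth J.
#' @param scaling scaling (lowpass) filter; symlet-4 by default.
#' @return List with `W` (list of detail coefficient vectors, levels
#'   1..J), `V` (final scaling coefficients) and the filters used.
#' @export
modwt <- function(x, nLevels = 4, scaling = SYM4_SCALING) {
  n <- length(x)
  L <- length(scaling)
  if (n < 2^nLevels * L)
    stop("series too short for ", nLevels, "-level MODWT with an L = ",
         L, " filter")
  g <- scaling / sqrt(2)
  h <- qmf(scaling) / sqrt(2)
  W <- vector("list", nLevels)
  V <- x
  for (j in seq_len(nLevels)) {
    s <- 2^(j - 1L)
    W[[j]] <- circFilt(V, h, s)
    V <- circFilt(V, g, s)
  }
  list(W = W, V = V, nLevels = nLevels, scaling = scaling)
}

# Invert one MODWT stage: recover level-(j-1) scaling coefficients from
# level-j detail and scaling coefficients.
imodwtStage <- function(Wj, Vj, j, scaling) {
  g <- scaling / sqrt(2)
  h <- qmf(scaling) / sqrt(2)
  s <- 2^(j - 1L)
  circFilt(Wj, h, s, synthesis = TRUE) +
    circFilt(Vj, g, s, synthesis = TRUE)
}

#' MODWT multiresolution analysis (MRA)
#'
#' Decomposes a series into additive detail components D_1..D_J plus the
#' final smooth S_J: each detail is obtained by inverting the transform
#' with all other coefficient vectors zeroed. The components sum to the
#' input exactly (to machine precision). Detail D_j carries the nominal
#' octave band \eqn{[f_s/2^{j+1}, f_s/2^j]}.
#'
#' @param x numeric series.
#' @param nLevels decomposition depth J.
#' @param scaling scaling filter; symlet-4 by default.
#' @return List with `details` (list of J series), `smooth` (series) and
#'   `nLevels`.
#' @examples
#' x <- sin(2 * pi * 1.2 * (0:599) / 30)
#' m <- modwtMra(x)
#' max(abs(Reduce(`+`, m$details) + m$smooth - x)) # ~ 1e-15
#' @export
modwtMra <- function(x, nLevels = 4, scaling = SYM4_SCALING) {
  dec <- modwt(x, nLevels, scaling)
  n <- length(x)
  zero <- numeric(n)
  reconstructFrom <- function(W, V) {
    for (j in rev(seq_len(nLevels)))
      V <- imodwtStage(W[[j]], V, j, scaling)
    V
  }
  details <- vector("list", nLevels)
  for (j in seq_len(nLevels)) {
    Wz <- rep(list(zero), nLevels)
    Wz[[j]] <- dec$W[[j]]
    details[[j]] <- reconstructFrom(Wz, zero)
  }
  smooth <- reconstructFrom(rep(list(zero), nLevels), dec$V)
  list(details = details, smooth = smooth, nLevels = nLevels)
}
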