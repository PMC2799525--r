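# Lupas COILS sliding-window coiled-coil propensity.
#
# A window of `window` residues is scored under each of the 7 heptad frames
# as the geometric mean of per-residue propensity weights; each residue
# keeps the best score over every (window placement, frame) covering it,
# and the score is converted to a probability by comparing Gaussian score
# distributions fitted to coiled-coil and globular sequences.

# MTIDK propensity matrix (relative residue frequencies at heptad positions
# a..g), transcribed from the COILS distribution (Lupas, Van Dyke & Stock
# 1991; ncoils "new.mat").  Zero entries are floored at 1e-4 so that
# geometric means stay defined; the floor is far below every genuine entry.
COILS_MTIDK <- local({
  m <- matrix(c(
    # a      b      c      d      e      f      g
    3.167, 0.297, 0.398, 3.902, 0.585, 0.501, 0.483,  # L
    2.597, 0.098, 0.345, 0.894, 0.514, 0.471, 0.431,  # I
    1.665, 0.403, 0.386, 0.949, 0.211, 0.342, 0.360,  # V
    2.240, 0.370, 0.480, 1.409, 0.541, 0.772, 0.663,  # M
    0.531, 0.076, 0.403, 0.662, 0.189, 0.106, 0.013,  # F
    1.417, 0.090, 0.122, 1.659, 0.190, 0.130, 0.155,  # Y
    0.045, 0.275, 0.578, 0.216, 0.211, 0.426, 0.156,  # G
    1.297, 1.551, 1.084, 2.612, 0.377, 1.248, 0.877,  # A
    1.375, 2.639, 1.763, 0.191, 1.815, 1.961, 2.795,  # K
    0.659, 1.163, 1.210, 0.031, 1.358, 1.937, 1.798,  # R
    0.347, 0.275, 0.679, 0.395, 0.294, 0.579, 0.213,  # H
    0.262, 3.496, 3.108, 0.998, 5.685, 2.494, 3.048,  # E
    0.030, 2.352, 2.268, 0.237, 0.663, 1.620, 1.448,  # D
    0.179, 2.114, 1.778, 0.631, 2.550, 1.578, 2.526,  # Q
    0.835, 1.475, 1.534, 0.039, 1.722, 2.456, 2.280,  # N
    0.382, 0.583, 1.052, 0.419, 0.525, 0.916, 0.628,  # S
    0.169, 0.702, 0.955, 0.654, 0.791, 0.843, 0.647,  # T
    0.824, 0.022, 0.308, 0.152, 0.180, 0.156, 0.044,  # C
    0.240, 0.000, 0.000, 0.456, 0.019, 0.000, 0.000,  # W
    0.000, 0.008, 0.000, 0.013, 0.000, 0.000, 0.000), # P
    nrow = 20, byrow = TRUE,
    dimnames = list(c("L", "I", "V", "M", "F", "Y", "G", "A", "K", "R",
                      "H", "E", "D", "Q", "N", "S", "T", "C", "W", "P"),
                    letters[1:7]))
  pmax(m, 1e-4)
})

# Gaussian score-distribution parameters (coiled-coil vs globular) per
# window length, transcribed from the same COILS distribution (unweighted
# MTIDK fits).
COILS_GAUSS <- list(
  `14` = list(cc_mean = 1.89, cc_sd = 0.30, glob_mean = 0.77, glob_sd = 0.20),
  `21` = list(cc_mean = 1.79, cc_sd = 0.24, glob_mean = 0.92, glob_sd = 0.22),
  `28` = list(cc_mean = 1.74, cc_sd = 0.20, glob_mean = 0.86, glob_sd = 0.18))

# prior odds of a globular over a coiled-coil window, as in the original
# probability conversion
COILS_GLOB_PRIOR <- 30

#' The embedded COILS propensity matrix
#'
#' @param name matrix identifier; only `"MTIDK"` is embedded.  Any 20 x 7
#'   positive matrix with residue rownames and columns a..g can be passed
#'   to the scoring functions instead.
#' @return A 20 x 7 numeric matrix.
#' @export
coils_matrix <- function(name = "MTIDK") {
  if (!identical(name, "MTIDK"))
    stop("coils_matrix: only the MTIDK matrix is embedded")
  COILS_MTIDK
}

coils_gauss <- function(window) {
  g <- COILS_GAUSS[[as.character(window)]]
  if (is.null(g)) {
    warning("no score-distribution fit for window ", window,
            "; using the 14-residue parameters")
    g <- COILS_GAUSS[["14"]]
  }
  g
}

matrix_weights <- function(aa, heptad, matrix) {
  idx <- match(aa, rownames(matrix))
  w <- numeric(length(aa))
  known <- !is.na(idx)
  w[known] <- matrix[cbind(idx[known], heptad[known])]
  if (any(!known)) {
    warning("unknown residue(s) scored at the matrix minimum: ",
            paste(unique(aa[!known]), collapse = ","))
    w[!known] <- min(matrix)
  }
  w
}

#' Score one window under one heptad frame
#'
#' The geometric mean of matrix weights for each residue at its heptad
#' position: `(prod w_i)^(1/window)`.  Frame `f` places the first residue
#' of the window at heptad position `f + 1` (0 = position a).
#'
#' @param seq amino-acid string.
#' @param start 1-based window start.
#' @param frame heptad frame offset, 0..6.
#' @param window window length (default 14).
#' @param matrix propensity matrix (default [coils_matrix()]).
#' @return The window score (positive scalar).
#' @export
window_score <- function(seq, start, frame, window = 14L,
                         matrix = coils_matrix()) {
  stopifnot(frame %in% 0:6)
  aa <- strsplit(toupper(seq), "")[[1]]
  if (start < 1L || start + window - 1L > length(aa))
    stop("window_score: window does not fit the sequence")
  i <- start:(start + window - 1L)
  heptad <- (frame + (i - start)) %% 7L + 1L
  w <- matrix_weights(aa[i], heptad, matrix)
  exp(mean(log(w)))
}

#' COILS coiled-coil propensity profile
#'
#' Every residue is assigned the best score over all (window placement,
#' frame) combinations covering it, and the score is converted to a
#' coiled-coil probability `Gcc / (Gcc + 30 * Gglob)` using Gaussian score
#' densities for coiled-coil and globular sequences at this window length.
#'
#' @param seq amino-acid string (or [protein_record()]).
#' @param window window length in residues (default 14).
#' @param matrix propensity matrix (default the embedded MTIDK).
#' @param id sequence identifier for the profile.
#' @return A data frame of class `coil_profile` with columns
#'   `position, residue, score, probability, best_frame`.
#' @export
coils_profile <- function(seq, window = 14L, matrix = coils_matrix(),
                          id = "seq") {
  if (inherits(seq, "protein_record")) { id <- seq$id; seq <- seq$sequence }
  aa <- strsplit(toupper(seq), "")[[1]]
  n <- length(aa)
  if (n < window) {
    warning("coils_profile: sequence shorter than the window; empty profile")
    out <- data.frame(position = integer(0), residue = character(0),
                      score = numeric(0), probability = numeric(0),
                      best_frame = integer(0))
    attr(out, "id") <- id
    class(out) <- c("coil_profile", "data.frame")
    return(out)
  }
  logm <- log(matrix)
  idx <- match(aa, rownames(matrix))
  unknown <- is.na(idx)
  if (any(unknown))
    warning("coils_profile: unknown residue(s) scored at the matrix minimum: ",
            paste(unique(aa[unknown]), collapse = ","))
  minlog <- log(min(matrix))
  best <- rep(-Inf, n)
  best_frame <- integer(n)
  for (s in 1:(n - window + 1L)) {
    span <- s:(s + window - 1L)
    ii <- idx[span]
    for (f in 0:6) {
      heptad <- (f + span - s) %% 7L + 1L
      lw <- ifelse(is.na(ii), minlog, logm[cbind(ii, heptad)])
      sc <- mean(lw)
      upd <- span[best[span] < sc]
      if (length(upd)) {
        best[upd] <- sc
        best_frame[upd] <- f
      }
    }
  }
  score <- exp(best)
  g <- coils_gauss(window)
  gcc <- stats::dnorm(score, g$cc_mean, g$cc_sd)
  gg <- stats::dnorm(score, g$glob_mean, g$glob_sd)
  prob <- gcc / (gcc + COILS_GLOB_PRIOR * gg)
  out <- data.frame(position = seq_len(n), residue = aa, score = score,
                    probability = prob, best_frame = best_frame)
  attr(out, "id") <- id
  attr(out, "window") <- window
  class(out) <- c("coil_profile", "data.frame")
  out
}

#' @export
print.coil_profile <- function(x, ...) {
  cat("<coil_profile>", attr(x, "id"), "-", nrow(x), "residues; max p =",
      if (nrow(x)) sprintf("%.3f", max(x$probability)) else "NA", "\n")
  invisible(x)
}

#' Summarise a coil profile over annotated protein regions
#'
#' @param profile a [coils_profile()] result.
#' @param regions data frame with `name, start, end` in protein residue
#'   coordinates.
#' @return Data frame `name, start, end, max_probability,
#'   mean_probability`.
#' @export
align_profile_to_regions <- function(profile, regions) {
  if (!nrow(regions))
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), max_probability = numeric(0),
                      mean_probability = numeric(0)))
  n <- nrow(profile)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 1L || e > n || e < s)
      stop("align_profile_to_regions: region '", regions$name[i],
           "' outside the protein")
    p <- profile$probability[s:e]
    data.frame(name = regions$name[i], start = s, end = e,
               max_probability = max(p), mean_probability = mean(p))
  })
  do.call(rbind, rows)
}

#' Cross-species peak concordance within one region
#'
#' The fraction of species whose coil profile reaches at least `threshold`
#' probability inside the region.
#'
#' @param profiles a list of [coils_profile()] results (one per species).
#' @param region list or one-row data frame with `start, end` in protein
#'   coordinates.
#' @param threshold probability threshold (default 0.9).
#' @return Fraction in `[0, 1]`.
#' @export
region_peak_concordance <- function(profiles, region, threshold = 0.9) {
  hits <- vapply(profiles, function(p) {
    e <- min(region$end, nrow(p))
    max(p$probability[region$start:e]) >= threshold
  }, logical(1))
  mean(hits)
}
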