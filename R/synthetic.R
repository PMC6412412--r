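#' Specification for synthetic PSSM datasets
#'
#' Describes a two-class collection of synthetic PSSM profiles used to
#' validate the pipeline offline. Negatives are pure i.i.d. Gaussian noise
#' matrices; positives superimpose a sinusoidal signal along the sequence
#' axis — `amplitude * sin(2 * pi * position / period)` — on a random subset
#' of residue columns. The signal is periodic in position by construction,
#' so it concentrates in a few Fourier coefficients of the Gram matrix: the
#' structure the FFT descriptor is designed to detect, with partial power
#' left for the DCT and covariance extractors.
#'
#' @param n_pos,n_neg Class sizes (positives carry label 1).
#' @param length_range Sequence-length range, drawn uniformly; default
#'   50-300 (profiles outside 50-5000 residues are conventionally filtered
#'   out of SIP benchmarks).
#' @param signal_period Period, in positions, of the class-1 sinusoid
#'   (default 8).
#' @param signal_amplitude Peak amplitude of the sinusoid (default 1; 0
#'   makes the classes exchangeable).
#' @param noise_sd Standard deviation of the Gaussian background (default 1).
#' @param n_signal_cols How many of the 20 residue columns carry the signal
#'   (default 10).
#' @param seed Integer seed for [generate_dataset()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 100L, n_neg = 100L,
                           length_range = c(50L, 300L),
                           signal_period = 8, signal_amplitude = 1,
                           noise_sd = 1, n_signal_cols = 10L, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length_range[[1]] >= 2L,
            length_range[[1]] <= length_range[[2]],
            signal_period >= 2, signal_amplitude >= 0, noise_sd > 0,
            n_signal_cols >= 1L, n_signal_cols <= 20L)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 signal_period = signal_period,
                 signal_amplitude = signal_amplitude, noise_sd = noise_sd,
                 n_signal_cols = as.integer(n_signal_cols),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic PSSM dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `profiles` (list of [pssm_profile()]) and `labels`
#'   (0/1 integer vector, positives first).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed)
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  profiles <- lapply(seq_along(labels), function(i) {
    lens <- seq(spec$length_range[[1]], spec$length_range[[2]])
    n <- lens[[sample.int(length(lens), 1L)]]
    m <- matrix(stats::rnorm(n * 20L, sd = spec$noise_sd), nrow = n)
    if (labels[[i]] == 1L && spec$signal_amplitude > 0) {
      cols <- sample(20L, spec$n_signal_cols)
      wave <- spec$signal_amplitude * sin(2 * pi * seq_len(n) / spec$signal_period)
      m[, cols] <- m[, cols] + wave
    }
    seq_chars <- sample(AA_CANONICAL, n, replace = TRUE)
    pssm_profile(m, paste(seq_chars, collapse = ""),
                 protein_id = sprintf("%s%04d", c("neg", "pos")[labels[[i]] + 1L], i),
                 source = "synthetic")
  })
  list(profiles = profiles, labels = labels)
}

#' Write synthetic profiles as PSI-BLAST ASCII fixtures
#'
#' Writes one `<protein_id>.pssm` file per profile (the dialect
#' [parse_psiblast_pssm()] reads back exactly) plus a `labels.tsv` table.
#'
#' @param dataset A list from [generate_dataset()] (fields `profiles`,
#'   `labels`).
#' @param dir Output directory (created if missing).
#' @return Tibble with columns `id`, `label`, `path`, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(dataset$profiles, function(p) {
    path <- file.path(dir, paste0(p$protein_id, ".pssm"))
    write_psiblast_pssm(p, path)
    path
  }, character(1))
  idx <- tibble::tibble(
    id = vapply(dataset$profiles, `[[`, character(1), "protein_id"),
    label = dataset$labels, path = paths)
  utils::write.table(idx[, c("id", "label")], file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(idx)
}
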