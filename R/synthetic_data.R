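# Seeded generators for CLIP-like tag sets, matched random controls and
# simulated fluorescence-polarization titrations.  Every generator is a
# pure function of its spec (including the seed): a single global seed
# derives one substream per tag, so per-tag output does not depend on
# generation order.

.default_base_freqs <- c(A = 0.29, C = 0.21, G = 0.21, U = 0.29)

#' Specification for a synthetic CLIP-like tag generator
#'
#' Describes the study conditions for a simulated HITS-CLIP tag set: tag
#' number and length, background base composition, and an optional
#' embedded pair of motif copies at a controlled intervening distance.
#' Embedding overwrites the background (lengths stay exact, so controls
#' can be length-matched), placing two copies of \code{embed_motif}
#' separated by a spacing drawn uniformly (or per \code{spacing_probs})
#' from \code{spacing_range}.
#'
#' Defaults mirror in vivo CLIP tags for T-STAR: 40-nt tags, mouse-like
#' background composition (A 0.29, C 0.21, G 0.21, U 0.29), UAAA motif
#' pairs spaced 20-30 nt apart in half of the tags.
#'
#' @param n_tags number of tags.
#' @param length_mean,length_sd tag length distribution (nt); lengths are
#'   rounded and floored at 1.
#' @param base_frequencies named probabilities over A, C, G, U summing
#'   to 1 (within 1e-9).
#' @param embed_fraction fraction of tags in [0, 1] receiving a motif pair.
#' @param embed_motif motif written twice into embedded tags (RNA
#'   alphabet).
#' @param spacing_range integer vector \code{c(min, max)}: intervening
#'   nucleotides between the two motif copies.
#' @param spacing_probs optional probabilities over
#'   \code{spacing_range[1]:spacing_range[2]} (default uniform).
#' @param seed integer seed.
#' @return A validated list of class \code{tag_generator_spec}.
#' @export
tag_generator_spec <- function(n_tags,
                               length_mean = 40, length_sd = 0,
                               base_frequencies = .default_base_freqs,
                               embed_fraction = 0,
                               embed_motif = "UAAA",
                               spacing_range = c(20L, 30L),
                               spacing_probs = NULL,
                               seed = 1L) {
  stopifnot(n_tags >= 0, length_mean > 0, length_sd >= 0,
            embed_fraction >= 0, embed_fraction <= 1)
  base_frequencies <- base_frequencies[c("A", "C", "G", "U")]
  if (anyNA(base_frequencies))
    stop("base_frequencies must be named with A, C, G, U")
  if (abs(sum(base_frequencies) - 1) > 1e-9)
    stop("base_frequencies must sum to 1 (within 1e-9)")
  spacing_range <- as.integer(round(spacing_range))
  stopifnot(length(spacing_range) == 2L, spacing_range[1] >= 0,
            spacing_range[2] >= spacing_range[1])
  spacings <- spacing_range[1]:spacing_range[2]
  if (is.null(spacing_probs)) spacing_probs <- rep(1, length(spacings))
  stopifnot(length(spacing_probs) == length(spacings),
            all(spacing_probs >= 0), sum(spacing_probs) > 0)
  embed_motif <- normalize_alphabet(embed_motif, "RNA", quiet = TRUE)
  if (grepl("N", embed_motif, fixed = TRUE))
    stop("embed_motif must not contain N")
  structure(list(n_tags = as.integer(n_tags),
                 length_mean = length_mean, length_sd = length_sd,
                 base_frequencies = base_frequencies,
                 embed_fraction = embed_fraction,
                 embed_motif = as.character(embed_motif),
                 spacings = spacings,
                 spacing_probs = spacing_probs / sum(spacing_probs),
                 seed = as.integer(seed)),
            class = "tag_generator_spec")
}

# one RNG substream seed per item, derived from the global seed so that
# item i is reproducible regardless of how many items are generated
.substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

.random_bases <- function(n, freqs) {
  sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = freqs)
}

#' Generate a synthetic CLIP-like tag set
#'
#' Background residues are drawn i.i.d. from the spec's base frequencies.
#' For \code{embed_fraction} of the tags (a seeded random subset of
#' exactly \code{round(n_tags * embed_fraction)} tags) two copies of the
#' motif are written over the background at a sampled intervening
#' distance.  Bit-reproducible for a fixed seed.
#'
#' @param spec a \code{\link{tag_generator_spec}}.
#' @return A \code{tag_set}; attribute \code{truth} is a data frame with
#'   one row per embedded tag (\code{index}, \code{start} of the first
#'   motif copy, 0-based, and \code{spacing}).
#' @export
generate_tags <- function(spec) {
  stopifnot(inherits(spec, "tag_generator_spec"))
  n <- spec$n_tags
  m <- nchar(spec$embed_motif)
  seeds <- .substream_seeds(spec$seed, n + 1L)
  set.seed(seeds[n + 1L])
  n_embed <- round(n * spec$embed_fraction)
  embed_idx <- if (n_embed > 0) sort(sample.int(n, n_embed)) else integer()
  embed <- seq_len(n) %in% embed_idx
  motif_chars <- strsplit(spec$embed_motif, "")[[1]]
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    li <- max(1L, as.integer(round(stats::rnorm(1, spec$length_mean,
                                                spec$length_sd))))
    chars <- .random_bases(li, spec$base_frequencies)
    if (embed[i]) {
      s <- sample(spec$spacings, 1L, prob = spec$spacing_probs)
      need <- 2L * m + s
      if (li < need)
        stop(sprintf(
          "tag %d (length %d) too short for motif pair with spacing %d (needs %d nt)",
          i, li, s, need))
      p0 <- sample.int(li - need + 1L, 1L) - 1L   # 0-based start
      chars[(p0 + 1):(p0 + m)] <- motif_chars
      chars[(p0 + m + s + 1):(p0 + need)] <- motif_chars
      truth[[i]] <- data.frame(index = i, start = p0, spacing = s)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  out <- tag_set(seqs, ids = sprintf("synthetic_tag_%d", seq_len(n)),
                 name = "synthetic_tags")
  attr(out, "truth") <- do.call(rbind, truth[!vapply(truth, is.null,
                                                     logical(1))])
  out
}

#' Generate a length-matched random control set
#'
#' One i.i.d. random sequence per requested length, emulating randomly
#' selected genomic regions of the same sizes as a CLIP tag set.
#'
#' @param lengths integer vector of sequence lengths (nt).
#' @param base_frequencies named probabilities over A, C, G, U (default
#'   mouse-like composition).
#' @param seed integer seed.
#' @return A \code{tag_set}.
#' @export
generate_control <- function(lengths,
                             base_frequencies = .default_base_freqs,
                             seed = 1L) {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  lengths <- as.integer(lengths)
  if (any(lengths < 0)) stop("negative length requested")
  base_frequencies <- base_frequencies[c("A", "C", "G", "U")]
  if (anyNA(base_frequencies) || abs(sum(base_frequencies) - 1) > 1e-9)
    stop("base_frequencies must be named A,C,G,U and sum to 1")
  seeds <- .substream_seeds(seed, length(lengths))
  seqs <- vapply(seq_along(lengths), function(i) {
    set.seed(seeds[i])
    paste(.random_bases(lengths[i], base_frequencies), collapse = "")
  }, character(1))
  tag_set(seqs, ids = sprintf("control_%d", seq_along(lengths)),
          name = "synthetic_control")
}

#' Specification for a simulated fluorescence-polarization titration
#'
#' Defaults mirror a standard plate design: a two-fold serial dilution of
#' protein from 200 uM down (15 points) plus a zero-protein well, with the
#' labelled RNA probe at 0.2 uM.  Polarization units are arbitrary
#' (typically mP); defaults of 50 (free probe) to 200 (saturated) span a
#' realistic dynamic range.
#'
#' @param true_kd dissociation constant (uM), > 0.
#' @param f_free,f_bound polarization at zero protein and at saturation
#'   (must differ).
#' @param rna_total labelled RNA concentration (uM).
#' @param concentrations protein concentrations (uM), must include 0.
#' @param noise_sd Gaussian noise added to each signal (polarization
#'   units).
#' @param model binding isotherm used to simulate, see
#'   \code{\link{predict_signal}}.
#' @param seed integer seed.
#' @return A validated list of class \code{titration_spec}.
#' @export
titration_spec <- function(true_kd, f_free = 50, f_bound = 200,
                           rna_total = 0.2,
                           concentrations = c(0, 200 / 2^(14:0)),
                           noise_sd = 0,
                           model = c("quadratic", "hyperbolic"),
                           seed = 1L) {
  model <- match.arg(model)
  stopifnot(true_kd > 0, rna_total > 0, noise_sd >= 0,
            all(concentrations >= 0))
  if (!any(concentrations == 0))
    stop("concentrations must include 0 (free-probe reference)")
  if (f_bound == f_free) stop("f_bound must differ from f_free")
  structure(list(true_kd = true_kd, f_free = f_free, f_bound = f_bound,
                 rna_total = rna_total,
                 concentrations = sort(unique(concentrations)),
                 noise_sd = noise_sd, model = model,
                 seed = as.integer(seed)),
            class = "titration_spec")
}

#' Simulate a fluorescence-polarization titration
#'
#' Signals are binding-model predictions (\code{\link{predict_signal}})
#' plus i.i.d. Gaussian noise; deterministic for a fixed seed.
#'
#' @param spec a \code{\link{titration_spec}}.
#' @return An \code{\link{fp_titration}} with attribute \code{true_kd}.
#' @export
generate_fp_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  mu <- predict_signal(spec$concentrations, kd = spec$true_kd,
                       f_free = spec$f_free, f_bound = spec$f_bound,
                       rna_total = spec$rna_total, model = spec$model)
  set.seed(spec$seed)
  sig <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
  out <- fp_titration(spec$concentrations, sig, rna_total = spec$rna_total)
  attr(out, "true_kd") <- spec$true_kd
  out
}
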