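# Monte-Carlo sampling of alternative ancestral sequences ("near-ancestors")
# from per-site posterior distributions under relative-probability thresholds.

#' Sample alternative ancestral sequences from a posterior matrix
#'
#' For each threshold `theta`, an (approximately) equal share of the `n`
#' requested sequences is drawn site-independently: at each unmasked site,
#' residues whose posterior is at least `theta` times the site's maximum
#' posterior are eligible, and one is drawn with probability proportional to
#' its posterior among the eligible set. Masked sites are emitted as `-`.
#' The most-probable sequence is appended afterwards if it was not drawn, so
#' the returned set holds `n` or `n + 1` sequences and always contains the
#' most-probable ancestor. Sampling is with replacement; duplicates are
#' retained so that frequency statistics stay unbiased.
#'
#' Randomness is consumed site by site in column order, with the vector of
#' per-threshold draws for a site taken in one block; the same
#' `(posterior, n, thresholds, seed)` always yields byte-identical output.
#'
#' @param post A `posterior_matrix`.
#' @param n Total number of sampled sequences across thresholds (>= 1).
#' @param thresholds Relative-probability thresholds in (0, 1].
#' @param seed Mandatory integer seed.
#' @param absolute Use absolute posterior thresholds instead of
#'   thresholds relative to the per-site maximum (off by default).
#' @return An `ancestor_set`: `node`, `samples` (tibble with `sequence`,
#'   `threshold`, `log_posterior`, `is_most_probable`), `most_probable`
#'   (an `ancestral_sequence`), `thresholds`, `n_requested`, `seed`.
#' @export
sample_ancestors <- function(post, n = 5000L, thresholds = c(0.2, 0.5),
                             seed, absolute = FALSE) {
  if (missing(seed) || is.null(seed)) abort("a seed is required for sampling")
  n <- as.integer(n)
  if (n < 1) abort("n must be >= 1")
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("thresholds must lie in (0, 1]")
  }
  set.seed(as.integer(seed))
  mp <- most_probable_sequence(post)
  n_thr <- length(thresholds)
  quota <- rep(n %/% n_thr, n_thr)
  rem <- n - sum(quota)
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  L <- nrow(post$probs)
  un <- which(!post$gap_mask)
  # residue draws: sites outermost, one block of draws per (site, threshold)
  chars <- matrix(GAP, nrow = n, ncol = L)
  logp <- matrix(0, nrow = n, ncol = length(un))
  offsets <- c(0L, cumsum(quota))
  for (si in seq_along(un)) {
    s <- un[si]
    p <- post$probs[s, ]
    pmax_s <- max(p)
    for (ti in seq_len(n_thr)) {
      cut <- if (absolute) thresholds[ti] else thresholds[ti] * pmax_s
      elig <- which(p >= cut)
      rows <- (offsets[ti] + 1L):offsets[ti + 1L]
      if (length(elig) == 1L) {
        draw <- rep(elig, length(rows))
      } else {
        draw <- sample(elig, length(rows), replace = TRUE, prob = p[elig])
      }
      chars[rows, s] <- AA[draw]
      logp[rows, si] <- log(p[draw])
    }
  }
  seqs <- apply(chars, 1, paste, collapse = "")
  samples <- tibble(
    sequence = seqs,
    threshold = rep(thresholds, quota),
    log_posterior = rowSums(logp),
    is_most_probable = seqs == mp$sequence
  )
  if (!any(samples$is_most_probable)) {
    mp_logp <- sum(log(post$max_posterior[un]))
    samples <- bind_rows(samples, tibble(
      sequence = mp$sequence, threshold = NA_real_,
      log_posterior = mp_logp, is_most_probable = TRUE))
  }
  structure(
    list(node = post$node, samples = samples, most_probable = mp,
         thresholds = thresholds, n_requested = n, seed = as.integer(seed),
         gap_mask = post$gap_mask),
    class = "ancestor_set")
}

#' @export
print.ancestor_set <- function(x, ...) {
  cat(sprintf("<ancestor_set> node %s: %d sequences (thresholds %s, seed %d)\n",
              x$node, nrow(x$samples),
              paste(x$thresholds, collapse = "/"), x$seed))
  invisible(x)
}

#' Per-position residue frequencies across a sampled ancestor set
#'
#' Reports, for each named catalytic position, the fraction of sampled
#' sequences carrying each residue. Positions mapped to masked (ancestrally
#' absent) sites are reported with `present = FALSE` and no frequencies.
#'
#' @param set An `ancestor_set`.
#' @param sites A `site_map` (see [map_reference_positions()]).
#' @return Tibble with `label`, `column`, `present`, `residue`, `frequency`;
#'   frequencies sum to 1 within each present position.
#' @export
summarize_site_variability <- function(set, sites) {
  if (nrow(set$samples) == 0) abort("empty ancestor set")
  seqm <- do.call(rbind, strsplit(set$samples$sequence, "", fixed = TRUE))
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    col <- sites$column[i]
    if (set$gap_mask[col]) {
      return(tibble(label = sites$label[i], column = col, present = FALSE,
                    residue = NA_character_, frequency = NA_real_))
    }
    tab <- table(seqm[, col])
    tibble(label = sites$label[i], column = col, present = TRUE,
           residue = names(tab),
           frequency = as.numeric(tab) / nrow(seqm)) %>%
      arrange(dplyr::desc(.data$frequency))
  })
}

#' Write a sampled ancestor set as FASTA
#'
#' Headers follow `node|sample_<k>|logP=<value>`; the most-probable sequence
#' (when appended) is labelled `node|most_probable`.
#'
#' @param set An `ancestor_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_ancestor_set_fasta <- function(set, path) {
  s <- set$samples
  hdr <- sprintf("%s|sample_%d|logP=%.6f", set$node, seq_len(nrow(s)),
                 s$log_posterior)
  hdr[is.na(s$threshold)] <- sprintf("%s|most_probable", set$node)
  xs <- Biostrings::AAStringSet(s$sequence)
  names(xs) <- hdr
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
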