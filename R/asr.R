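# Empirical-Bayes marginal ancestral reconstruction.
#
# Posteriors are computed by a single two-pass (inside/outside) algorithm:
# the pruning pass gives, for every node, the likelihood of the data below
# it; the outside pass propagates the likelihood of everything above it from
# the root. For a reversible model this equals re-rooting at each queried
# node, at O(n) total cost instead of O(n^2).

# Outside pass for one category. Takes the down-pass result and returns
# per-node outside vectors (20 x S) with cumulative log scale.
outside_pass <- function(idx, down, freqs) {
  S <- ncol(down$partial[[idx$root]])
  O <- vector("list", idx$n_node)
  oscale <- vector("list", idx$n_node)
  O[[idx$root]] <- matrix(freqs, 20, S)
  oscale[[idx$root]] <- numeric(S)
  for (u in rev(idx$postorder)) {
    if (u <= idx$n_tip) next
    kids <- idx$children[[u]]
    M <- lapply(kids, function(w) down$P[[w]] %*% down$partial[[w]])
    for (j in seq_along(kids)) {
      v <- kids[j]
      prod_other <- O[[u]]
      sc <- oscale[[u]]
      for (jj in seq_along(kids)) {
        if (jj == j) next
        prod_other <- prod_other * M[[jj]]
        sc <- sc + down$scalelog[[kids[jj]]]
      }
      Ov <- crossprod(down$P[[v]], prod_other)
      mx <- apply(Ov, 2, max)
      mx[mx == 0] <- 1
      O[[v]] <- Ov / rep(mx, each = 20)
      oscale[[v]] <- sc + log(mx)
    }
  }
  list(O = O, oscale = oscale)
}

# Posterior matrices (sites x 20) for all internal nodes, category-averaged.
marginal_posteriors_engine <- function(idx, pat, model) {
  pl <- pattern_loglik(idx, pat$states, model)
  K <- model$k
  out <- vector("list", K)
  for (cat in seq_len(K)) {
    out[[cat]] <- outside_pass(idx, pl$down[[cat]], model$freqs)
  }
  internal <- setdiff(seq_len(idx$n_node), seq_len(idx$n_tip))
  posts <- list()
  Sp <- ncol(pat$states)
  for (v in internal) {
    un <- array(0, dim = c(20, Sp, K))
    off <- matrix(0, K, Sp)
    for (cat in seq_len(K)) {
      d <- pl$down[[cat]]
      un[, , cat] <- out[[cat]]$O[[v]] * d$partial[[v]]
      off[cat, ] <- out[[cat]]$oscale[[v]] + d$scalelog[[v]]
    }
    m <- apply(off, 2, max)
    comb <- matrix(0, 20, Sp)
    for (cat in seq_len(K)) {
      comb <- comb + un[, , cat] * rep(exp(off[cat, ] - m), each = 20)
    }
    tot <- colSums(comb)
    probs <- t(comb / rep(tot, each = 20))
    colnames(probs) <- AA
    # Site-likelihood consistency: summing the unnormalised posterior over
    # states reproduces the site likelihood; kept for the invariant test.
    posts[[idx$labels[v]]] <- list(
      probs = probs[pat$pattern_of_site, , drop = FALSE],
      site_loglik_check = (log(tot) + m - log(K))[pat$pattern_of_site]
    )
  }
  list(posts = posts, site_loglik = pl$site[pat$pattern_of_site])
}

#' Marginal posterior amino-acid probabilities at an internal node
#'
#' Empirical-Bayes marginal reconstruction: for each alignment column, the
#' posterior distribution over the 20 amino acids at the queried ancestor,
#' integrating over all other internal states and rate categories. Sites
#' judged ancestrally absent by [ancestral_gap_mask()] carry no distribution
#' (rows of `NA`).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param aln A `protein_alignment`.
#' @param model An `aa_subst_model`.
#' @param node Internal node label (e.g. `"N1"`). `NULL` returns a list of
#'   posterior matrices for every internal node.
#' @param gap_threshold Fraction of descendant leaves that must be non-gap
#'   for the site to be considered present in the ancestor (default 0.5;
#'   exactly the threshold counts as present).
#' @return A `posterior_matrix` (or named list of them): `node`, `probs`
#'   (sites x 20), `gap_mask` (TRUE = ancestrally absent), `max_posterior`
#'   per site.
#' @export
marginal_posteriors <- function(tree, aln, model, node = NULL,
                                gap_threshold = 0.5) {
  tree <- label_internal_nodes(tree)
  idx <- tree_index(tree)
  if (!is.null(node)) {
    v <- node_number(tree, node)
    if (v <= idx$n_tip) abort(paste0("node '", node, "' is a leaf, not an ancestor"))
  }
  pat <- aln_patterns(aln, tree$tip.label)
  eng <- marginal_posteriors_engine(idx, pat, model)
  build_one <- function(label) {
    mask <- ancestral_gap_mask(tree, aln, label, threshold = gap_threshold)
    probs <- eng$posts[[label]]$probs
    probs[mask, ] <- NA_real_
    structure(
      list(node = label, probs = probs, gap_mask = mask,
           max_posterior = ifelse(mask, NA_real_, apply(probs, 1, max)),
           site_loglik = eng$site_loglik,
           site_loglik_check = eng$posts[[label]]$site_loglik_check),
      class = "posterior_matrix")
  }
  if (is.null(node)) {
    labels <- tree$node.label
    setNames(lapply(labels, build_one), labels)
  } else {
    build_one(node)
  }
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("<posterior_matrix> node %s: %d sites (%d masked), mean max-posterior %.3f\n",
              x$node, nrow(x$probs), sum(x$gap_mask),
              mean(x$max_posterior, na.rm = TRUE)))
  invisible(x)
}

#' Ancestral presence/absence mask by descendant majority
#'
#' A site is called ancestrally absent at a node when fewer than `threshold`
#' of the node's descendant leaves are non-gap there (exactly the threshold
#' counts as present). This automates the usual post-hoc curation of
#' C-terminal and other indels from the ancestor's progeny; insertion and
#' deletion are not modelled in the substitution process itself.
#'
#' @param tree Rooted `phylo`.
#' @param aln A `protein_alignment`.
#' @param node Internal node label.
#' @param threshold Presence threshold on the non-gap fraction.
#' @return Logical vector, one per column; `TRUE` = ancestrally absent.
#' @export
ancestral_gap_mask <- function(tree, aln, node, threshold = 0.5) {
  tree <- label_internal_nodes(tree)
  idx <- tree_index(tree)
  v <- node_number(tree, node)
  if (v <= idx$n_tip) abort("gap mask is defined for internal nodes")
  tips <- descendant_tips(idx, v)
  m <- unclass(aln)[tree$tip.label[tips], , drop = FALSE]
  frac_present <- colMeans(m != GAP)
  frac_present < threshold
}

#' Most-probable ancestral sequence from a posterior matrix
#'
#' Per-site argmax of the posterior, ties broken by the canonical
#' alphabetical amino-acid order; masked sites become `-`.
#'
#' @param post A `posterior_matrix`.
#' @return An `ancestral_sequence`: `node`, `sequence` (alignment
#'   coordinates), `max_posterior` per site, `mean_confidence` (mean of the
#'   per-site maxima over unmasked sites).
#' @export
most_probable_sequence <- function(post) {
  n <- nrow(post$probs)
  seqc <- rep(GAP, n)
  un <- which(!post$gap_mask)
  if (length(un) > 0) {
    # max.col with ties.method = "first" honours the alphabetical tie-break
    # because columns are in canonical order.
    seqc[un] <- AA[max.col(post$probs[un, , drop = FALSE], ties.method = "first")]
  }
  structure(
    list(node = post$node,
         sequence = paste(seqc, collapse = ""),
         max_posterior = post$max_posterior,
         mean_confidence = reconstruction_confidence(post)),
    class = "ancestral_sequence")
}

#' @export
print.ancestral_sequence <- function(x, ...) {
  cat(sprintf("<ancestral_sequence> node %s (%d sites, mean confidence %.3f)\n",
              x$node, nchar(x$sequence), x$mean_confidence))
  invisible(x)
}

#' Mean reconstruction confidence at a node
#'
#' Arithmetic mean of the per-site maximum posterior probabilities over
#' unmasked sites.
#'
#' @param post A `posterior_matrix`.
#' @return Mean confidence in (0, 1].
#' @export
reconstruction_confidence <- function(post) {
  un <- !post$gap_mask
  if (!any(un)) abort("all sites masked: no reconstruction confidence defined")
  mean(post$max_posterior[un])
}

#' Confidence summary across internal nodes
#'
#' @param posts Named list of `posterior_matrix` objects (as returned by
#'   [marginal_posteriors()] with `node = NULL`).
#' @return Tibble with `node`, `n_sites`, `n_masked`, `mean_confidence`,
#'   `min_confidence`, `frac_above_0.95`.
#' @export
confidence_summary <- function(posts) {
  purrr::map_dfr(posts, function(p) {
    un <- !p$gap_mask
    tibble(node = p$node,
           n_sites = length(p$gap_mask),
           n_masked = sum(p$gap_mask),
           mean_confidence = mean(p$max_posterior[un]),
           min_confidence = min(p$max_posterior[un]),
           frac_above_0.95 = mean(p$max_posterior[un] >= 0.95))
  })
}

#' Write posterior matrices as TSV
#'
#' One row per (node, site) with the 20 posterior columns; masked sites are
#' flagged and carry NA probabilities.
#'
#' @param posts A `posterior_matrix` or list of them.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_posteriors <- function(posts, path) {
  if (inherits(posts, "posterior_matrix")) posts <- list(posts)
  df <- purrr::map_dfr(posts, function(p) {
    d <- as_tibble(p$probs)
    d <- mutate(d, node = p$node, site = seq_len(nrow(p$probs)),
                masked = p$gap_mask, .before = 1)
    d
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ancestral sequences as FASTA
#'
#' @param seqs List of `ancestral_sequence` objects.
#' @param path Output FASTA path.
#' @param ungapped Drop `-` characters (masked sites) before writing?
#' @return `path`, invisibly.
#' @export
write_ancestors_fasta <- function(seqs, path, ungapped = FALSE) {
  if (inherits(seqs, "ancestral_sequence")) seqs <- list(seqs)
  ss <- vapply(seqs, function(s) s$sequence, "")
  if (ungapped) ss <- gsub(GAP, "", ss, fixed = TRUE)
  set <- Biostrings::AAStringSet(ss)
  names(set) <- vapply(seqs, function(s) s$node, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
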