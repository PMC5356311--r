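# Felsenstein pruning machinery.
#
# Leaf states: residues are indicator vectors; gaps and ambiguity letters are
# missing data (all-ones vectors), the PAML convention. Partial likelihoods
# are scaled per site at every internal node, with log scale factors
# accumulated, so 300+-column alignments cannot underflow.

# Encode the alignment as integer states (0 = missing) and compress identical
# site patterns. Results are required to be identical to uncompressed
# evaluation, so this is purely a speed device.
aln_patterns <- function(aln, tip_labels) {
  missing_tips <- setdiff(tip_labels, rownames(aln))
  if (length(missing_tips) > 0) {
    abort(paste0("leaf without a sequence in the alignment: ",
                 paste(missing_tips, collapse = ", ")))
  }
  m <- unclass(aln)[tip_labels, , drop = FALSE]
  states <- matrix(match(m, AA), nrow = nrow(m))
  states[is.na(states)] <- 0L
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pattern_of_site <- match(key, key[first])
  list(states = states[, first, drop = FALSE],
       weights = as.vector(table(factor(pattern_of_site,
                                        levels = seq_len(sum(first))))),
       pattern_of_site = pattern_of_site,
       n_sites = ncol(states))
}

# Down (pruning) pass for one rate scaling d = t*r per branch.
# Returns per-node partials (20 x S) and per-node cumulative log scale (S).
prune_down <- function(idx, states, model, rate) {
  S <- ncol(states)
  partial <- vector("list", idx$n_node)
  scalelog <- vector("list", idx$n_node)
  Pmat <- vector("list", idx$n_node)
  for (v in idx$postorder) {
    if (v != idx$root) {
      Pmat[[v]] <- transition_matrix_raw(model, idx$blen[v] * rate)
    }
    if (v <= idx$n_tip) {
      L <- matrix(0, 20, S)
      s <- states[v, ]
      obs <- s > 0
      L[cbind(s[obs], which(obs))] <- 1
      L[, !obs] <- 1
      partial[[v]] <- L
      scalelog[[v]] <- numeric(S)
    } else {
      L <- matrix(1, 20, S)
      sc <- numeric(S)
      for (w in idx$children[[v]]) {
        L <- L * (Pmat[[w]] %*% partial[[w]])
        sc <- sc + scalelog[[w]]
      }
      mx <- apply(L, 2, max)
      mx[mx == 0] <- 1
      partial[[v]] <- L / rep(mx, each = 20)
      scalelog[[v]] <- sc + log(mx)
    }
  }
  list(partial = partial, scalelog = scalelog, P = Pmat)
}

# Per-pattern log-likelihood for each category, and combined (mean over
# categories). Returns list(by_cat: K x S matrix, site: S vector).
pattern_loglik <- function(idx, states, model) {
  K <- model$k
  by_cat <- matrix(NA_real_, K, ncol(states))
  down <- vector("list", K)
  for (cat in seq_len(K)) {
    d <- prune_down(idx, states, model, model$rates[cat])
    root <- d$partial[[idx$root]]
    by_cat[cat, ] <- log(colSums(model$freqs * root)) + d$scalelog[[idx$root]]
    down[[cat]] <- d
  }
  m <- apply(by_cat, 2, max)
  site <- m + log(colMeans(exp(sweep(by_cat, 2, m))))
  list(by_cat = by_cat, site = site, down = down)
}

#' Log-likelihood of an alignment on a tree under a substitution model
#'
#' Computes the alignment's log-likelihood by the pruning algorithm, with
#' discrete-gamma rate categories averaged with equal weights and gaps or
#' ambiguity letters treated as missing data.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param aln A `protein_alignment` containing every leaf.
#' @param model An `aa_subst_model`.
#' @return A `likelihood_result`: `loglik` (total), `site_loglik` (one value
#'   per alignment column), plus the model and tree used.
#' @export
log_likelihood <- function(tree, aln, model) {
  tree <- label_internal_nodes(tree)
  idx <- tree_index(tree)
  pat <- aln_patterns(aln, tree$tip.label)
  pl <- pattern_loglik(idx, pat$states, model)
  site <- pl$site[pat$pattern_of_site]
  structure(
    list(loglik = sum(site), site_loglik = site,
         model = model, tree = tree),
    class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("<likelihood_result> logL = %.6f over %d sites (%s)\n",
              x$loglik, length(x$site_loglik), x$model$name))
  invisible(x)
}

#' Optimize branch lengths by coordinate-wise 1-D search
#'
#' Each branch in turn is optimised by bounded 1-D search (lengths clamped to
#' `[1e-8, 20]`), for at least two full sweeps and until the total
#' log-likelihood improves by less than `tol`. The reported log-likelihood
#' sequence is non-decreasing.
#'
#' @param tree Rooted `phylo`.
#' @param aln A `protein_alignment`.
#' @param model An `aa_subst_model`.
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_sweeps Maximum number of full sweeps.
#' @return List with `tree` (updated lengths), `result` (a
#'   `likelihood_result`), and `trace` (log-likelihood after each sweep).
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_sweeps = 10L) {
  if (tol <= 0) abort("tol must be > 0")
  tree <- label_internal_nodes(tree)
  pat <- aln_patterns(aln, tree$tip.label)
  eval_total <- function(phy) {
    idx <- tree_index(phy)
    sum(pattern_loglik(idx, pat$states, model)$site * pat$weights)
  }
  lo <- 1e-8; hi <- 20
  tree$edge.length <- pmin(pmax(tree$edge.length, lo), hi)
  cur <- eval_total(tree)
  trace <- cur
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (b in seq_along(tree$edge.length)) {
      f <- function(x) {
        phy2 <- tree
        phy2$edge.length[b] <- x
        eval_total(phy2)
      }
      opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
      if (opt$objective > cur) {
        tree$edge.length[b] <- opt$maximum
        cur <- opt$objective
      }
    }
    trace <- c(trace, cur)
    if (sweep >= 2 && trace[sweep + 1] - trace[sweep] < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("branch-length optimization did not converge; returning best so far")
  }
  list(tree = tree, result = log_likelihood(tree, aln, model), trace = trace)
}

#' Estimate the gamma shape parameter by maximum likelihood
#'
#' Bounded 1-D optimisation of the log-likelihood over the gamma shape
#' (log scale internally). Hitting the upper bound is flagged: the data are
#' then effectively rate-homogeneous.
#'
#' @param tree Rooted `phylo`.
#' @param aln A `protein_alignment`.
#' @param model An `aa_subst_model` (its exchangeabilities/frequencies are
#'   kept; its `alpha` is replaced during the search).
#' @param bounds Lower/upper bounds for alpha.
#' @param k Number of gamma categories used during the search.
#' @return List with `alpha` (the estimate), `loglik`, and `at_upper_bound`
#'   (logical: effectively rate-homogeneous).
#' @export
estimate_gamma_shape <- function(tree, aln, model, bounds = c(0.05, 100),
                                 k = 4L) {
  if (!(bounds[1] > 0 && bounds[1] < bounds[2])) {
    abort("bounds must satisfy 0 < lo < hi")
  }
  tree <- label_internal_nodes(tree)
  pat <- aln_patterns(aln, tree$tip.label)
  idx <- tree_index(tree)
  f <- function(la) {
    m <- build_model(model$name, model$frequency_mode,
                     aln = if (model$frequency_mode == "observed") aln,
                     alpha = exp(la), k = k)
    sum(pattern_loglik(idx, pat$states, m)$site * pat$weights)
  }
  opt <- optimize(f, log(bounds), maximum = TRUE, tol = 1e-6)
  alpha <- exp(opt$maximum)
  at_upper <- alpha > bounds[2] * 0.98
  if (at_upper) {
    message("estimated gamma shape is at the upper bound: effectively rate-homogeneous")
  }
  list(alpha = alpha, loglik = opt$objective, at_upper_bound = at_upper)
}

#' Compare substitution models by AIC
#'
#' Fits each named model on the fixed tree (optionally estimating the gamma
#' shape and/or re-optimising branch lengths) and ranks by
#' `AIC = 2k - 2 logL`, counting as free parameters the gamma shape (if
#' estimated) and the branch lengths (if optimised). Ties are broken by the
#' order in which the model names were supplied.
#'
#' @param tree Rooted `phylo`.
#' @param aln A `protein_alignment`.
#' @param model_names At least two of `"WAG"`, `"LG"`, `"Dayhoff"`.
#' @param estimate_alpha Estimate a gamma shape per model?
#' @param optimize_lengths Re-optimise branch lengths per model?
#' @param k Gamma categories when estimating alpha.
#' @return A `model_comparison` tibble: `model`, `loglik`, `n_par`, `aic`,
#'   `alpha`, `rank` (1 = preferred), sorted by rank.
#' @export
compare_models <- function(tree, aln, model_names,
                           estimate_alpha = FALSE,
                           optimize_lengths = FALSE, k = 4L) {
  if (length(model_names) < 2) abort("compare_models needs at least 2 model names")
  bad <- setdiff(model_names, SUPPORTED_MODELS)
  if (length(bad) > 0) {
    abort(paste0("unknown model name(s): ", paste(bad, collapse = ", ")))
  }
  tree <- label_internal_nodes(tree)
  rows <- purrr::map_dfr(model_names, function(nm) {
    phy <- tree
    alpha <- NULL
    n_par <- 0
    if (estimate_alpha) {
      base <- build_model(nm)
      est <- estimate_gamma_shape(phy, aln, base, k = k)
      alpha <- est$alpha
      n_par <- n_par + 1
    }
    m <- build_model(nm, alpha = alpha, k = k)
    if (optimize_lengths) {
      ob <- optimize_branch_lengths(phy, aln, m)
      phy <- ob$tree
      n_par <- n_par + length(phy$edge.length)
    }
    ll <- log_likelihood(phy, aln, m)$loglik
    tibble(model = nm, loglik = ll, n_par = n_par,
           aic = 2 * n_par - 2 * ll,
           alpha = if (is.null(alpha)) NA_real_ else alpha)
  })
  rows$rank <- rank(rows$aic, ties.method = "first")
  out <- arrange(rows, .data$rank)
  structure(out, class = c("model_comparison", class(out)))
}

#' Write a model comparison as a JSON report
#'
#' @param cmp A `model_comparison` (see [compare_models()]).
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_model_comparison <- function(cmp, path) {
  jsonlite::write_json(as.data.frame(cmp), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Per-site log-likelihood export
#'
#' @param result A `likelihood_result`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_site_loglik <- function(result, path) {
  df <- tibble(site = seq_along(result$site_loglik),
               log_likelihood = result$site_loglik)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
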