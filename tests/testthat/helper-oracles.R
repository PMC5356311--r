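# Shared fixtures and independent oracles. Every oracle here deliberately
# avoids the package's own computational route.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_alignment <- function(ids, L, seed) {
  set.seed(seed)
  as_alignment(setNames(
    replicate(length(ids), paste(sample(AA20, L, TRUE), collapse = "")),
    ids))
}

# Scaled-and-squared Taylor series matrix exponential (independent of the
# eigendecomposition route used by the package).
expm_series <- function(M, n_terms = 30L, n_square = 10L) {
  Ms <- M / 2^n_square
  P <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in seq_len(n_terms)) {
    term <- term %*% Ms / i
    P <- P + term
  }
  for (i in seq_len(n_square)) P <- P %*% P
  P
}

# Numerical-quadrature oracle for mean-of-bin discrete gamma rates.
gamma_rates_quadrature <- function(alpha, k) {
  bounds <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  sapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                     bounds[i], bounds[i + 1],
                     rel.tol = 1e-10)$value * k
  })
}

# Brute-force enumeration oracle for the rooted 4-leaf tree
# ((A:bl[A],B:bl[B])N2:bl[N2],(C:bl[C],D:bl[D])N3:bl[N3])N1;
# states: 4 x L integer matrix of leaf states (rows A,B,C,D).
# Enumerates the two internal-state assignments (u at N2, v at N3)
# explicitly; the root state r is summed as an explicit vector product.
brute_force_4leaf <- function(states, bl, model) {
  K <- model$k
  L <- ncol(states)
  lik <- matrix(0, K, L)
  postN2 <- array(0, dim = c(L, 20, K))
  for (k in seq_len(K)) {
    P <- lapply(bl, function(t) transition_matrix(model, t, k))
    for (s in seq_len(L)) {
      la <- P$A[, states[1, s]]
      lb <- P$B[, states[2, s]]
      lc <- P$C[, states[3, s]]
      ld <- P$D[, states[4, s]]
      for (u in 1:20) {
        for (v in 1:20) {
          joint <- sum(model$freqs * P$N2[, u] * P$N3[, v]) *
            la[u] * lb[u] * lc[v] * ld[v]
          lik[k, s] <- lik[k, s] + joint
          postN2[s, u, k] <- postN2[s, u, k] + joint
        }
      }
    }
  }
  site_lik <- colMeans(lik)
  post <- apply(postN2, c(1, 2), mean)
  post <- post / rowSums(post)
  list(site_loglik = log(site_lik), posterior_N2 = post)
}

make_4leaf_instance <- function(seed, L = 10, alpha = NULL, k = 1L) {
  set.seed(seed)
  bl <- as.list(setNames(round(runif(6, 0.02, 0.8), 4),
                         c("A", "B", "C", "D", "N2", "N3")))
  nwk <- sprintf("((A:%f,B:%f)N2:%f,(C:%f,D:%f)N3:%f)N1;",
                 bl$A, bl$B, bl$N2, bl$C, bl$D, bl$N3)
  states <- matrix(sample.int(20, 4 * L, TRUE), 4)
  aln <- as_alignment(setNames(
    apply(states, 1, function(r) paste(AA20[r], collapse = "")),
    c("A", "B", "C", "D")))
  model <- build_model("WAG", alpha = alpha, k = k)
  list(tree = ape::read.tree(text = nwk), aln = aln, states = states,
       bl = bl, model = model)
}

# Grid-search SSE oracle for the single-site Michaelis-Menten fit.
mm_grid_oracle <- function(curve, km_range, kcat_range, n_grid = 200L) {
  kms <- exp(seq(log(km_range[1]), log(km_range[2]), length.out = n_grid))
  kcats <- seq(kcat_range[1], kcat_range[2], length.out = n_grid)
  best <- list(sse = Inf)
  for (km in kms) {
    pred_base <- curve$substrate_uM / (km + curve$substrate_uM)
    for (kc in kcats) {
      sse <- sum((curve$rate_per_s - kc * pred_base)^2)
      if (sse < best$sse) best <- list(sse = sse, Km = km, kcat = kc)
    }
  }
  best
}

# Hand-built posterior matrix for sampling tests.
make_post <- function(probs, gap_mask = rep(FALSE, nrow(probs)),
                      node = "NX") {
  colnames(probs) <- AA20
  probs[gap_mask, ] <- NA_real_
  structure(
    list(node = node, probs = probs, gap_mask = gap_mask,
         max_posterior = ifelse(gap_mask, NA_real_,
                                suppressWarnings(apply(probs, 1, max)))),
    class = "posterior_matrix")
}

# Single-character edit of a sequence string at given columns.
with_residues <- function(seq, cols, residues) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[cols] <- residues
  paste(ch, collapse = "")
}
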