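#' Supported empirical amino-acid replacement models
#' @export
SUPPORTED_MODELS <- c("WAG", "LG", "Dayhoff")

# Parse a PAML-layout .dat file: 19 lower-triangle rows of exchangeabilities
# followed by the 20 equilibrium frequencies, in PAML residue order.
# Returns S (20x20 symmetric) and freqs, both re-indexed to the package's
# alphabetical residue order.
parse_paml_dat <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  nums <- lapply(strsplit(trimws(txt), "\\s+"), as.numeric)
  tri <- nums[1:19]
  if (any(vapply(tri, length, 1L) != 1:19)) {
    abort(paste0("malformed PAML matrix file: ", path))
  }
  freqs <- nums[[20]]
  if (length(freqs) != 20) abort(paste0("expected 20 frequencies in ", path))
  S <- matrix(0, 20, 20, dimnames = list(AA_PAML, AA_PAML))
  for (i in 2:20) S[i, 1:(i - 1)] <- tri[[i - 1]]
  S <- S + t(S)
  names(freqs) <- AA_PAML
  list(S = S[AA, AA], freqs = freqs[AA] / sum(freqs))
}

model_data_path <- function(name) {
  file <- c(WAG = "wag.dat", LG = "lg.dat", Dayhoff = "dayhoff.dat")[name]
  system.file("extdata", "models", file, package = "peroxasr", mustWork = TRUE)
}

#' Build an amino-acid substitution model
#'
#' Assembles a reversible continuous-time Markov model from a bundled
#' empirical exchangeability matrix, equilibrium frequencies (model defaults
#' or `+F` frequencies observed in an alignment), and an optional discrete
#' gamma model of among-site rate variation. The rate matrix `Q = S diag(pi)`
#' is normalised so that one unit of branch length equals one expected
#' substitution per site.
#'
#' @param name One of `"WAG"`, `"LG"`, `"Dayhoff"`.
#' @param frequency_mode `"model"` (bundled defaults) or `"observed"`
#'   (`+F`: counted from the alignment's non-gap residues with a pseudocount
#'   of 1 per amino acid).
#' @param aln A `protein_alignment`, required when `frequency_mode =
#'   "observed"`.
#' @param alpha Gamma shape for among-site rate variation, or `NULL` for
#'   homogeneous rates.
#' @param k Number of discrete gamma categories (ignored when `alpha` is
#'   `NULL`).
#' @param pseudocount Pseudocount per amino acid for observed frequencies.
#' @return An `aa_subst_model`: exchangeabilities `S`, frequencies `freqs`,
#'   normalised generator `Q`, `alpha`, `k`, category `rates` (mean 1), and a
#'   cached eigendecomposition used for transition probabilities.
#' @export
build_model <- function(name, frequency_mode = c("model", "observed"),
                        aln = NULL, alpha = NULL, k = 4L, pseudocount = 1) {
  if (!name %in% SUPPORTED_MODELS) {
    abort(paste0("unknown model '", name, "'; supported: ",
                 paste(SUPPORTED_MODELS, collapse = ", ")))
  }
  frequency_mode <- match.arg(frequency_mode)
  dat <- parse_paml_dat(model_data_path(name))
  freqs <- dat$freqs
  if (frequency_mode == "observed") {
    if (is.null(aln)) abort("frequency_mode = 'observed' requires an alignment")
    freqs <- observed_frequencies(aln, pseudocount = pseudocount)
  }
  if (!is.null(alpha)) {
    if (alpha <= 0) abort("gamma shape alpha must be > 0")
    rates <- discrete_gamma_rates(alpha, k)
  } else {
    k <- 1L
    rates <- 1
  }
  Q <- dat$S %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(AA, AA)
  # Symmetric eigendecomposition of diag(sqrt(pi)) Q diag(1/sqrt(pi));
  # reversibility makes this exact and numerically stable.
  sq <- sqrt(freqs)
  B <- (Q * sq) / rep(sq, each = 20)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors / sq
  Uinv <- t(e$vectors) * rep(sq, each = 20)
  structure(
    list(name = name, frequency_mode = frequency_mode, S = dat$S,
         freqs = freqs, Q = Q, alpha = alpha, k = as.integer(k),
         rates = rates, eig = list(values = e$values, U = U, Uinv = Uinv)),
    class = "aa_subst_model")
}

observed_frequencies <- function(aln, pseudocount = 1) {
  chars <- as.vector(unclass(aln))
  counts <- table(factor(chars[chars %in% AA], levels = AA))
  counts <- as.numeric(counts) + pseudocount
  if (sum(counts > 0) < 2) {
    abort("degenerate observed frequencies: fewer than two amino acids present")
  }
  setNames(counts / sum(counts), AA)
}

#' Discrete-gamma rate categories (mean-of-bin discretisation)
#'
#' Splits the gamma(shape = alpha, mean = 1) density into `k` equal-probability
#' bins and uses each bin's conditional mean as its category rate, then
#' renormalises so the category mean is exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` non-decreasing positive rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (alpha <= 0) abort("gamma shape alpha must be > 0")
  k <- as.integer(k)
  if (k < 1) abort("k must be >= 1")
  if (k == 1) return(1)
  # Bin means via the incomplete-gamma identity:
  # E[X | a < X < b] * P(a < X < b) = F_{alpha+1}(b) - F_{alpha+1}(a)
  # for X ~ gamma(alpha, rate = alpha) (mean 1).
  bounds <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  upper <- pgamma(bounds[-1], shape = alpha + 1, rate = alpha)
  lower <- pgamma(bounds[-(k + 1)], shape = alpha + 1, rate = alpha)
  rates <- (upper - lower) * k
  rates / mean(rates)
}

#' Transition probability matrix P(t) for one rate category
#'
#' @param model An `aa_subst_model`.
#' @param t Branch length (expected substitutions/site at rate 1), >= 0.
#' @param category Rate category index (default 1).
#' @return Row-stochastic 20x20 matrix `P(t * r_category)`.
#' @export
transition_matrix <- function(model, t, category = 1L) {
  if (t < 0) abort("branch length must be >= 0")
  r <- model$rates[category]
  if (is.na(r)) abort("invalid rate category")
  P <- transition_matrix_raw(model, t * r)
  dimnames(P) <- list(AA, AA)
  P
}

# P(d) from the cached eigendecomposition; rows renormalised after clipping
# tiny negative round-off.
transition_matrix_raw <- function(model, d) {
  e <- model$eig
  P <- e$U %*% (exp(e$values * d) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' @export
print.aa_subst_model <- function(x, ...) {
  gamma <- if (is.null(x$alpha)) "rate-homogeneous"
           else sprintf("+G (alpha = %.4g, K = %d)", x$alpha, x$k)
  cat(sprintf("<aa_subst_model> %s (%s frequencies), %s\n",
              x$name, x$frequency_mode, gamma))
  invisible(x)
}
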