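# Catalytic-site typing of class-II peroxidases.
#
# Two substrate oxidation sites drive the family labels: the Mn(2+)-binding
# acidic triad (two glutamates and one aspartate near the heme propionate)
# and the exposed catalytic tryptophan that oxidises nonphenolic lignin by
# long-range electron transfer. The label is a pure function of the triad
# state and tryptophan presence:
#
#   triad state  \ Trp      present          absent
#   typical  (3 exact)      VP               MnP
#   atypical (2 exact,      VP-atypical      MnP-atypical
#             third non-basic)
#   blocked  (2 exact,      LiP              GP
#             third R/K) or none
#
# A basic residue (Arg/Lys) in the mismatching triad position blocks cation
# binding outright, while a non-basic mismatch leaves a weakly functional
# ("atypical") site.

#' Catalytic-site rules for a peroxidase family
#'
#' Positions are labels resolved through a `site_map`; defaults follow the
#' mature-ancestor numbering of the fungal class-II family (Glu37, Glu41,
#' Asp183 triad; Trp172).
#'
#' @param triad Named character vector: position label -> required residue.
#' @param trp Named character vector of length 1: tryptophan position label
#'   -> required residue.
#' @param basic Residues counted as basic (blocking) in a mismatching triad
#'   position; histidine is deliberately excluded.
#' @return A `site_rules` object.
#' @export
site_rules <- function(triad = c("37" = "E", "41" = "E", "183" = "D"),
                       trp = c("172" = "W"),
                       basic = c("R", "K")) {
  stopifnot(length(trp) == 1, all(nchar(c(triad, trp)) == 1))
  structure(list(triad = triad, trp = trp, basic = basic),
            class = "site_rules")
}

#' Read/write catalytic-site rules as YAML
#'
#' @param path YAML file with fields `triad` (map position -> residue),
#'   `trp` (map), and optionally `basic` (list).
#' @return A `site_rules` object.
#' @export
read_site_rules <- function(path) {
  y <- yaml::read_yaml(path)
  site_rules(triad = unlist(y$triad), trp = unlist(y$trp),
             basic = if (!is.null(y$basic)) unlist(y$basic) else c("R", "K"))
}

#' @rdname read_site_rules
#' @param rules A `site_rules` object.
#' @return `path`, invisibly.
#' @export
write_site_rules <- function(rules, path) {
  yaml::write_yaml(list(triad = as.list(rules$triad),
                        trp = as.list(rules$trp),
                        basic = as.list(rules$basic)), path)
  invisible(path)
}

resolve_rule_columns <- function(sites, rules) {
  want <- c(names(rules$triad), names(rules$trp))
  miss <- setdiff(want, sites$label)
  if (length(miss) > 0) {
    abort(paste0("site map lacks positions required by the rules: ",
                 paste(miss, collapse = ", ")))
  }
  setNames(sites$column[match(want, sites$label)], want)
}

#' Classify the catalytic profile of one sequence
#'
#' Counts exact matches to the acidic-triad residues (glutamate vs aspartate
#' are distinguished), inspects the mismatching position for a basic
#' (blocking) residue, checks the catalytic tryptophan, and assigns the
#' peroxidase type. Positions that are gapped in the sequence count as
#' mismatches and are flagged.
#'
#' @param seq Sequence on alignment coordinates: a character string or an
#'   `ancestral_sequence`.
#' @param sites A `site_map` resolving the rule position labels.
#' @param rules A `site_rules` object.
#' @return A `catalytic_profile`: observed residues, `exact_triad_matches`
#'   (0-3), `third_position_basic`, `has_catalytic_trp`, `mn_site`
#'   (`typical`/`atypical`/`blocked`/`none`), `type`, `gapped_positions`.
#' @export
classify_catalytic_profile <- function(seq, sites, rules = site_rules()) {
  if (inherits(seq, "ancestral_sequence")) seq <- seq$sequence
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cols <- resolve_rule_columns(sites, rules)
  if (any(cols > length(chars))) abort("sequence shorter than mapped columns")
  observed <- setNames(chars[cols], names(cols))
  triad_obs <- observed[names(rules$triad)]
  match_ok <- triad_obs == rules$triad
  n_match <- sum(match_ok)
  gapped <- names(observed)[observed == GAP]
  mismatch_res <- triad_obs[!match_ok]
  third_basic <- n_match == 2 && mismatch_res %in% rules$basic
  mn_site <- if (n_match == 3) "typical"
    else if (n_match == 2 && third_basic) "blocked"
    else if (n_match == 2) "atypical"
    else "none"
  has_trp <- unname(observed[names(rules$trp)] == rules$trp)
  type <- peroxidase_type(mn_site, has_trp)
  structure(
    list(residues = observed, exact_triad_matches = as.integer(n_match),
         third_position_basic = isTRUE(third_basic),
         has_catalytic_trp = has_trp, mn_site = mn_site, type = type,
         gapped_positions = gapped),
    class = "catalytic_profile")
}

# Total mapping (mn_site, trp) -> type label.
peroxidase_type <- function(mn_site, has_trp) {
  switch(mn_site,
    typical  = if (has_trp) "VP" else "MnP",
    atypical = if (has_trp) "VP-atypical" else "MnP-atypical",
    blocked  = ,
    none     = if (has_trp) "LiP" else "GP",
    abort(paste0("unknown mn_site state: ", mn_site)))
}

#' @export
print.catalytic_profile <- function(x, ...) {
  cat(sprintf("<catalytic_profile> %s | triad %d/3 (%s)%s | Trp %s\n",
              x$type, x$exact_triad_matches, x$mn_site,
              if (x$third_position_basic) " basic-blocked" else "",
              if (x$has_catalytic_trp) "present" else "absent"))
  cat("  residues:", paste(names(x$residues), x$residues, sep = "=",
                           collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.catalytic_profile <- function(x, ...) {
  n_triad <- length(x$residues) - 1L
  tibble(position = names(x$residues), residue = unname(x$residues),
         role = c(rep("triad", n_triad), "trp"))
}

#' Partition a sampled ancestor set by catalytic profile
#'
#' Classifies every sampled sequence and partitions the set into the triad
#' subsets (`typical-triad`, `atypical`, `basic-blocked`, `other`), also
#' reporting per-type fractions.
#'
#' @param set An `ancestor_set`.
#' @param sites A `site_map`.
#' @param rules A `site_rules`.
#' @return An `ancestor_partition` list: `per_sample` tibble (sequence index,
#'   subset, type, trp), `subset_fractions`, `type_fractions` (both tibbles
#'   whose fractions sum to 1).
#' @export
partition_ancestor_set <- function(set, sites, rules = site_rules()) {
  if (nrow(set$samples) == 0) abort("empty ancestor set")
  per <- purrr::map_dfr(seq_len(nrow(set$samples)), function(i) {
    p <- classify_catalytic_profile(set$samples$sequence[i], sites, rules)
    subset <- switch(p$mn_site,
      typical = "typical-triad",
      atypical = "atypical",
      blocked = "basic-blocked",
      none = "other")
    tibble(sample = i, subset = subset, type = p$type,
           has_catalytic_trp = p$has_catalytic_trp,
           exact_triad_matches = p$exact_triad_matches)
  })
  frac <- function(x) {
    tab <- table(x)
    tibble(level = names(tab), n = as.integer(tab),
           fraction = as.numeric(tab) / length(x))
  }
  structure(
    list(per_sample = per,
         subset_fractions = frac(per$subset),
         type_fractions = frac(per$type)),
    class = "ancestor_partition")
}

#' @export
print.ancestor_partition <- function(x, ...) {
  cat("<ancestor_partition>\n")
  for (i in seq_len(nrow(x$type_fractions))) {
    cat(sprintf("  %-13s %.3f\n", x$type_fractions$level[i],
                x$type_fractions$fraction[i]))
  }
  invisible(x)
}
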