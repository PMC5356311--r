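#' Read a gapped protein alignment from FASTA
#'
#' Reads an aligned FASTA file into a `protein_alignment` object: a character
#' matrix (rows = sequences, columns = alignment positions) restricted to the
#' 20 amino-acid letters plus the gap character `-`. Ambiguity letters
#' (X, B, Z, J) are accepted and flagged; downstream likelihood machinery
#' treats them as missing data.
#'
#' @param path Path to a FASTA file.
#' @return A `protein_alignment`: character matrix with unique rownames (the
#'   record ids, input order preserved) and attribute `n_ambiguous`, the count
#'   of ambiguity letters seen on read.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort("empty FASTA file: no records")
  ids <- sub("\\s.*$", "", names(set))
  rows <- toupper(as.character(set))
  new_alignment(rows, ids)
}

new_alignment <- function(rows, ids) {
  lens <- nchar(rows)
  if (length(unique(lens)) > 1) {
    bad <- ids[lens != lens[1]][1]
    abort(paste0("alignment rows differ in length (offending id: ", bad, ")"))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- ids
  letters_seen <- unique(as.vector(m))
  bad <- setdiff(letters_seen, c(AA, GAP, AA_AMBIG))
  if (length(bad) > 0) {
    abort(paste0("illegal alignment characters: ", paste(bad, collapse = " ")))
  }
  n_amb <- sum(m %in% AA_AMBIG)
  if (n_amb > 0) {
    message(sprintf("read_alignment: %d ambiguous residue(s) (X/B/Z/J) treated as missing data downstream", n_amb))
  }
  structure(m, n_ambiguous = n_amb, class = c("protein_alignment", class(m)))
}

#' Build a protein alignment from named sequence strings
#'
#' @param x Named character vector of equal-length gapped sequences.
#' @return A `protein_alignment`.
#' @export
as_alignment <- function(x) {
  if (is.null(names(x)) || any(names(x) == "")) abort("sequences must be named")
  new_alignment(toupper(unname(x)), names(x))
}

#' Write a protein alignment to FASTA
#'
#' @param aln A `protein_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- rownames(aln)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d sequences x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Map reference residue numbers onto alignment columns
#'
#' Residue numbers are 1-based on the ungapped reference sequence (the field's
#' "Trp172"-style numbering); alignment columns are also reported 1-based.
#'
#' @param aln A `protein_alignment`.
#' @param reference_id Id of the reference row.
#' @param residue_numbers Integer vector of 1-based residue numbers on the
#'   ungapped reference.
#' @param labels Optional labels for the positions (default: the residue
#'   numbers as character).
#' @return A `site_map` tibble with columns `label`, `residue_number`,
#'   `column` (1-based alignment column) and `reference_residue`; attribute
#'   `reference_id` records the reference row.
#' @export
map_reference_positions <- function(aln, reference_id, residue_numbers,
                                    labels = as.character(residue_numbers)) {
  if (!reference_id %in% rownames(aln)) {
    abort(paste0("reference id not in alignment: ", reference_id))
  }
  row <- unclass(aln)[reference_id, ]
  nongap <- which(row != GAP)
  residue_numbers <- as.integer(residue_numbers)
  if (any(residue_numbers < 1)) abort("residue numbers must be >= 1")
  if (any(residue_numbers > length(nongap))) {
    abort(sprintf("residue number %d beyond ungapped reference length (%d)",
                  max(residue_numbers), length(nongap)))
  }
  cols <- nongap[residue_numbers]
  out <- tibble(
    label = labels,
    residue_number = residue_numbers,
    column = cols,
    reference_residue = row[cols]
  )
  structure(out, reference_id = reference_id,
            class = c("site_map", class(out)))
}

#' Percent identity between two aligned rows
#'
#' Identity is matches divided by the number of columns where both rows are
#' non-gap; the pair count is reported alongside.
#'
#' @param aln A `protein_alignment`.
#' @param id_a,id_b Sequence ids.
#' @return A list with `percent_identity` (0-100) and `aligned_pairs`.
#' @export
pairwise_identity <- function(aln, id_a, id_b) {
  for (id in c(id_a, id_b)) {
    if (!id %in% rownames(aln)) abort(paste0("unknown sequence id: ", id))
  }
  a <- unclass(aln)[id_a, ]
  b <- unclass(aln)[id_b, ]
  shared <- a != GAP & b != GAP
  n <- sum(shared)
  if (n == 0) return(list(percent_identity = NA_real_, aligned_pairs = 0L))
  list(percent_identity = 100 * sum(a[shared] == b[shared]) / n,
       aligned_pairs = as.integer(n))
}

#' All-pairs identity table
#'
#' @param aln A `protein_alignment`.
#' @param ids Optional subset of ids (default all).
#' @return Tibble with columns `id_a`, `id_b`, `percent_identity`,
#'   `aligned_pairs`, one row per unordered pair.
#' @export
identity_table <- function(aln, ids = rownames(aln)) {
  pairs <- utils::combn(ids, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    pi <- pairwise_identity(aln, pairs[1, k], pairs[2, k])
    tibble(id_a = pairs[1, k], id_b = pairs[2, k],
           percent_identity = pi$percent_identity,
           aligned_pairs = pi$aligned_pairs)
  })
}
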