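#' Labeled protein sequence sets
#'
#' `rbp_sequences` objects are plain data frames with columns `id`,
#' `residues`, `description` and `label` (1 = RBP, 0 = non-RBP, `NA` for
#' prediction-only input). All downstream encoders consume this shape.
#'
#' @param id character vector of unique record identifiers.
#' @param residues character vector of amino-acid strings.
#' @param label binary labels (0/1) or `NA`.
#' @param description optional free-text header remainders.
#' @return an `rbp_sequences` data frame.
#' @export
rbp_sequences <- function(id, residues, label = NA, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  out <- data.frame(
    id = id, residues = residues,
    description = rep_len(as.character(description), length(id)),
    label = rep_len(as.integer(label), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("rbp_sequences", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Parses a (multi-line) FASTA file into an [rbp_sequences] set. The record
#' id is the header token before the first whitespace; the remainder is kept
#' as `description`. Sequence lines are concatenated and uppercased. A
#' sequence line before the first header is a parse error naming the line;
#' duplicated ids are an error listing the duplicates; an empty file yields
#' an empty set with a warning.
#'
#' @param path path to a FASTA file.
#' @param label optional binary label attached to every record.
#' @return an [rbp_sequences] data frame, one row per record, in file order.
#' @export
read_fasta <- function(path, label = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  # pre-scan for sequence-before-header so the error names the line
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(rbp_sequences(character(0), character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA in ", path, ": sequence before first header at line ",
         nonblank[1])
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  rbp_sequences(id, as.character(set), label = label, description = desc)
}

#' Write sequences to FASTA
#'
#' Round-trips exactly with [read_fasta]: ids (plus descriptions, when
#' present) become headers and residues the sequence lines.
#'
#' @param seqs an [rbp_sequences] set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs$residues)
  names(set) <- ifelse(nzchar(seqs$description),
                       paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Remove nonstandard residues
#'
#' Codes outside the 20-letter standard alphabet (B, J, O, U, X, Z, stop
#' `*`, gap characters) are handled per `policy`: `"drop_residue"` deletes
#' the offending characters, `"drop_record"` rejects any sequence containing
#' one. Sequences that end up empty are rejected with reason
#' `"empty_after_sanitize"`. Rejections are returned in the `"rejected"`
#' attribute, a data frame of (id, reason).
#'
#' @param seqs an [rbp_sequences] set.
#' @param policy `"drop_residue"` (default) or `"drop_record"`.
#' @return the surviving [rbp_sequences]; rejected records in
#'   `attr(, "rejected")`.
#' @export
sanitize_sequences <- function(seqs, policy = c("drop_residue", "drop_record")) {
  policy <- match.arg(policy)
  bad_re <- "[^ACDEFGHIKLMNPQRSTVWY]"
  res <- toupper(seqs$residues)
  has_bad <- grepl(bad_re, res)
  reject <- data.frame(id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(seqs))
  if (policy == "drop_record") {
    keep <- !has_bad
    if (any(has_bad))
      reject <- rbind(reject, data.frame(id = seqs$id[has_bad],
                                         reason = "nonstandard_residue"))
  } else {
    res[has_bad] <- gsub(bad_re, "", res[has_bad])
  }
  empty <- keep & !nzchar(res)
  if (any(empty)) {
    reject <- rbind(reject, data.frame(id = seqs$id[empty],
                                       reason = "empty_after_sanitize"))
    keep <- keep & !empty
  }
  out <- seqs[keep, , drop = FALSE]
  out$residues <- res[keep]
  class(out) <- c("rbp_sequences", "data.frame")
  rownames(out) <- NULL
  attr(out, "rejected") <- reject
  out
}

#' Load a labeled two-class dataset from paired FASTA files
#'
#' Positives are labeled 1, negatives 0. If an id occurs in both files the
#' colliding records are namespaced as `pos:<id>` / `neg:<id>`. Records are
#' sanitized with the given policy before return.
#'
#' @param pos_path FASTA of positive (RBP) sequences.
#' @param neg_path FASTA of negative (non-RBP) sequences.
#' @param policy nonstandard-residue policy, see [sanitize_sequences].
#' @return an [rbp_sequences] set with labels; rejections in
#'   `attr(, "rejected")`.
#' @export
load_dataset <- function(pos_path, neg_path, policy = "drop_residue") {
  pos <- read_fasta(pos_path, label = 1)
  neg <- read_fasta(neg_path, label = 0)
  if (nrow(pos) == 0L) stop("no records in positive file: ", pos_path)
  if (nrow(neg) == 0L) stop("no records in negative file: ", neg_path)
  clash <- intersect(pos$id, neg$id)
  if (length(clash)) {
    pos$id[pos$id %in% clash] <- paste0("pos:", pos$id[pos$id %in% clash])
    neg$id[neg$id %in% clash] <- paste0("neg:", neg$id[neg$id %in% clash])
  }
  all <- rbind(pos, neg)
  class(all) <- c("rbp_sequences", "data.frame")
  rownames(all) <- NULL
  out <- sanitize_sequences(all, policy)
  message(sprintf("loaded %d positive + %d negative sequences (%d rejected)",
                  sum(out$label == 1), sum(out$label == 0),
                  nrow(attr(out, "rejected"))))
  out
}
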