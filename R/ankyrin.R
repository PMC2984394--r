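AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ar_required_cols <- c("protein", "identifier", "position", "sequence")

col_synonyms <- list(
  protein = c("protein", "protein_name", "name"),
  identifier = c("identifier", "id", "accession", "uniprot", "entry"),
  position = c("position", "repeat_position", "repeat", "pos"),
  sequence = c("sequence", "seq", "repeat_sequence"))

validate_ar_db <- function(db) {
  db$sequence <- toupper(db$sequence)
  db$position <- as.integer(db$position)
  bad <- grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"),
               db$sequence)
  if (any(bad))
    stop("sequence(s) outside the amino-acid alphabet (20 letters + X) at ",
         "row(s) ", paste(head(which(bad), 5L), collapse = ", "))
  if (any(is.na(db$position)) || any(db$position < 1L))
    stop("repeat positions must be integers >= 1")
  db$length <- nchar(db$sequence)
  # redundancy removal: keep the first record per (identifier, position)
  db <- db[!duplicated(db[c("identifier", "position")]), , drop = FALSE]
  rownames(db) <- NULL
  structure(db, class = c("ar_database", "data.frame"))
}

#' Read an ankyrin-repeat database
#'
#' Reads a collection of individual ankyrin repeats with provenance
#' (protein name, identifier, ordinal position of the repeat within its
#' protein, amino-acid sequence). Two dialects are accepted: tab- or
#' comma-delimited text with a header (column names are matched
#' case-insensitively against common synonyms; extra columns are carried
#' through untouched), and FASTA with `>identifier|protein|position`
#' headers. Records duplicated in (identifier, position) are collapsed
#' keeping the first, mirroring the redundancy removal applied when the
#' source databases were merged.
#'
#' @param path path to a TSV/CSV or FASTA file.
#' @param format `"auto"` (default; FASTA detected by a leading `>`),
#'   `"tsv"`, `"csv"` or `"fasta"`.
#' @return An `"ar_database"`: a data frame with columns `protein`,
#'   `identifier`, `position`, `sequence`, `length` (plus any extra input
#'   columns).
#' @seealso [write_ar_database()], [generate_ar_database()]
#' @export
read_ar_database <- function(path, format = c("auto", "tsv", "csv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && startsWith(first, ">")) "fasta"
              else if (length(first) && grepl("\t", first)) "tsv" else "csv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L)
      return(validate_ar_db(data.frame(protein = character(),
                                       identifier = character(),
                                       position = integer(),
                                       sequence = character())))
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != 3L))
      stop("malformed FASTA header (need 'identifier|protein|position') ",
           "at record ", which(nfield != 3L)[1])
    pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
    if (any(is.na(pos)))
      stop("non-numeric repeat position in FASTA header at record ",
           which(is.na(pos))[1])
    db <- data.frame(protein = vapply(parts, `[`, "", 2L),
                     identifier = vapply(parts, `[`, "", 1L),
                     position = pos,
                     sequence = as.character(seqs))
    return(validate_ar_db(db))
  }
  sep <- if (format == "tsv") "\t" else ","
  empty <- data.frame(protein = character(), identifier = character(),
                      position = integer(), sequence = character())
  raw <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                    comment.char = "#",
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE, quote = "\""),
                  error = function(e) {
                    if (grepl("no lines available", conditionMessage(e)))
                      return(empty)
                    stop(e)
                  })
  if (nrow(raw) == 0L)
    return(validate_ar_db(empty))
  lowered <- tolower(names(raw))
  for (canon in names(col_synonyms)) {
    hit <- which(lowered %in% col_synonyms[[canon]])
    if (length(hit) == 0L)
      stop("no '", canon, "' column found in ", path,
           " (header line 1; accepted names: ",
           paste(col_synonyms[[canon]], collapse = ", "), ")")
    names(raw)[hit[1]] <- canon
  }
  validate_ar_db(raw)
}

#' Write an ankyrin-repeat database as TSV
#'
#' @param db an `"ar_database"` (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ar_database <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Classify a single ankyrin repeat by FIH-target motifs
#'
#' Positions are 1-based from the repeat's N-terminus. The loop region of
#' the prototypical 33-residue repeat spans positions 25-33; an asparagine
#' there is the minimal requirement for FIH-catalysed hydroxylation.
#' Classes:
#' \describe{
#'   \item{`non_Asn`}{no asparagine at positions 25-33; not a target.}
#'   \item{`Asn_non_L8N`}{a loop asparagine, but none with a leucine eight
#'     residues upstream; an unlikely target.}
#'   \item{`L8N`}{some loop asparagine at position p has leucine at p - 8;
#'     a likely target.}
#' }
#' `L8N` repeats additionally matching the stringent consensus
#' `21-L(X)4(AC)(DEN)(ILV)N-29` (leucine 21, any residues 22-25, Ala/Cys
#' 26, Asp/Glu/Asn 27, Ile/Leu/Val 28, Asn 29) are flagged `strict`, the
#' most probable hydroxylation targets.
#'
#' @param sequence one-letter amino-acid string (case-insensitive), length
#'   >= 29.
#' @return List with elements `class` (one of the three labels) and
#'   `strict` (logical; `TRUE` only within `L8N`).
#' @examples
#' classify_repeat(paste0(strrep("A", 20), "LGGGGADVN", "GGGG"))
#' @export
classify_repeat <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 29L)
    stop("sequence of length ", n,
         " is unclassifiable (positional rules need >= 29 residues)")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  loop <- 25:min(33L, n)
  asn <- loop[ch[loop] == "N"]
  if (length(asn) == 0L)
    return(list(class = "non_Asn", strict = FALSE))
  l8 <- any(ch[asn - 8L] == "L")
  if (!l8)
    return(list(class = "Asn_non_L8N", strict = FALSE))
  strict <- n >= 29L && ch[21] == "L" &&
    ch[26] %in% c("A", "C") && ch[27] %in% c("D", "E", "N") &&
    ch[28] %in% c("I", "L", "V") && ch[29] == "N"
  list(class = "L8N", strict = strict)
}

#' Classify every repeat of a database
#'
#' Applies [classify_repeat()] to each record. Repeats too short to
#' classify (< 29 residues) get an `NA` class and are reported in a
#' warning.
#'
#' @param db an `"ar_database"`.
#' @return `db` with added columns `class` (factor `non_Asn`,
#'   `Asn_non_L8N`, `L8N`) and `strict` (logical).
#' @export
classify_ars <- function(db) {
  cls <- character(nrow(db)); strict <- logical(nrow(db))
  short <- nchar(db$sequence) < 29L
  cls[short] <- NA_character_
  for (i in which(!short)) {
    r <- classify_repeat(db$sequence[i])
    cls[i] <- r$class
    strict[i] <- r$strict
  }
  if (any(short))
    warning(sum(short), " repeat(s) shorter than 29 residues left unclassified")
  db$class <- factor(cls, levels = c("non_Asn", "Asn_non_L8N", "L8N"))
  db$strict <- strict
  db
}

#' Tabulate motif classes across a repeat database
#'
#' Summarises a classified database in the layout of the published census:
#' per class, the number of repeats, their percentage of all classified
#' repeats, and the number of distinct proteins (identifiers) contributing.
#' The strict-consensus subgroup of `L8N` is reported as its own row, and
#' loop-asparagine repeats (`L8N` plus `Asn_non_L8N`) as an aggregate.
#'
#' @param db a database classified by [classify_ars()].
#' @return An `"ar_class_table"` data frame with columns `group`,
#'   `repeats`, `percent`, `proteins`.
#' @export
tabulate_ar_classes <- function(db) {
  if (is.null(db$class)) db <- classify_ars(db)
  ok <- !is.na(db$class)
  d <- db[ok, , drop = FALSE]
  n <- nrow(d)
  row_for <- function(group, sel) {
    data.frame(group = group, repeats = sum(sel),
               percent = if (n > 0) 100 * sum(sel) / n else 0,
               proteins = length(unique(d$identifier[sel])))
  }
  out <- rbind(row_for("L8N", d$class == "L8N"),
               row_for("L8N_strict", d$class == "L8N" & d$strict),
               row_for("Asn_non_L8N", d$class == "Asn_non_L8N"),
               row_for("Asn_repeats",
                       d$class %in% c("L8N", "Asn_non_L8N")),
               row_for("non_Asn", d$class == "non_Asn"),
               data.frame(group = "total", repeats = n, percent = if (n > 0) 100 else 0,
                          proteins = length(unique(d$identifier))))
  structure(out, class = c("ar_class_table", "data.frame"))
}

#' Filter repeats by length
#'
#' The consensus and position-frequency summaries are restricted to repeats
#' of near-canonical length; by default 32-34 residues.
#'
#' @param db an `"ar_database"`.
#' @param min,max inclusive length bounds.
#' @return List with `db` (the retained records) and `excluded_fraction`.
#' @export
length_filter <- function(db, min = 32L, max = 34L) {
  if (min > max) stop("min must not exceed max")
  keep <- db$length >= min & db$length <= max
  list(db = db[keep, , drop = FALSE],
       excluded_fraction = if (nrow(db) > 0) mean(!keep) else 0)
}

pad_to_33 <- function(sequences) {
  # N-terminal alignment: truncate beyond 33, pad short repeats with X
  s <- substr(sequences, 1L, 33L)
  pad <- 33L - nchar(s)
  paste0(s, strrep("X", pmax(pad, 0L)))
}

#' Position-frequency matrix of aligned repeats
#'
#' Aligns repeats by their N-terminus at the canonical 33 positions
#' (shorter repeats padded with `X`, longer ones truncated) and tabulates
#' per-position residue frequencies. Each column sums to one; `X` occupies
#' its own row and never contributes to the consensus.
#'
#' @param db an `"ar_database"`, normally length-filtered to 32-34
#'   residues first.
#' @return An `"ar_pfm"`: a 21 x 33 matrix (rows: 20 amino acids + `X`)
#'   with attribute `n` (number of contributing repeats).
#' @export
ar_frequency_matrix <- function(db) {
  if (nrow(db) == 0L) stop("empty repeat collection")
  mat <- matrix(0, nrow = 21L, ncol = 33L,
                dimnames = list(residue = c(AA20, "X"), position = 1:33))
  chars <- strsplit(pad_to_33(db$sequence), "", fixed = TRUE)
  for (ch in chars) {
    idx <- match(ch, rownames(mat))
    mat[cbind(idx, 1:33)] <- mat[cbind(idx, 1:33)] + 1
  }
  mat <- mat / nrow(db)
  structure(mat, n = nrow(db), class = c("ar_pfm", class(mat)))
}

#' Consensus sequence of aligned repeats
#'
#' The modal residue at each of the 33 aligned positions (ties broken
#' alphabetically and flagged); padding `X` is ignored.
#'
#' @inheritParams ar_frequency_matrix
#' @return A 33-character string with attribute `ties`, the positions at
#'   which the mode was not unique.
#' @export
ar_consensus <- function(db) {
  pfm <- ar_frequency_matrix(db)
  aa <- pfm[AA20, , drop = FALSE]
  cons <- character(33L); ties <- integer(0)
  for (j in 1:33) {
    col <- aa[, j]
    top <- which(col == max(col))
    if (length(top) > 1L) ties <- c(ties, j)
    cons[j] <- AA20[top[1]]   # rows are alphabetical, so [1] breaks ties
  }
  structure(paste(cons, collapse = ""), ties = ties)
}

#' Per-position conservation from a frequency matrix
#'
#' Conservation is `1 -` the Shannon entropy of the column's residue
#' distribution normalised by its maximum (`log2(20)`); 1 means perfectly
#' conserved, 0 uniformly random. The `X` padding row is excluded and the
#' remaining frequencies renormalised.
#'
#' @param pfm an `"ar_pfm"` from [ar_frequency_matrix()].
#' @return Numeric vector of length 33 in `[0, 1]`.
#' @export
ar_conservation <- function(pfm) {
  aa <- pfm[AA20, , drop = FALSE]
  apply(aa, 2L, function(col) {
    tot <- sum(col)
    if (tot == 0) return(0)
    pr <- col[col > 0] / tot
    1 - sum(-pr * log2(pr)) / log2(20)
  })
}

#' Export a consensus sequence as single-record FASTA
#'
#' @param consensus string from [ar_consensus()].
#' @param path output path.
#' @param name FASTA record name.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path,
                                  name = "ankyrin_repeat_consensus") {
  set <- Biostrings::AAStringSet(stats::setNames(as.character(consensus),
                                                 name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
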