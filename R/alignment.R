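#' Read a multiple sequence alignment
#'
#' FASTA or Clustal input (via seqinr), returned as a character matrix of
#' aligned residues with one row per sequence. Gap characters (`-` and `.`)
#' are preserved as `-`; all rows must have equal length.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return object of class `Alignment`: list with `ids` and `mat`
#'   (n_seq x n_col uppercase character matrix).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  seqs <- toupper(unlist(aln$seq))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  ids <- sub("\\s.*$", "", aln$nam)
  if (any(duplicated(ids))) stop("duplicate sequence ids in alignment")
  mat <- do.call(rbind, strsplit(seqs, ""))
  mat[mat == "."] <- "-"
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat), class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", ncol(x$mat), "columns\n")
  invisible(x)
}

#' Map residue numbers of one sequence to alignment columns
#'
#' @param alignment an `Alignment`.
#' @param sequence_id row to map.
#' @param offset author number of the residue at ungapped position 1,
#'   minus 1 (so `res_id - offset` is the ungapped position).
#' @return integer vector: alignment column of each ungapped position.
#' @export
alignment_columns <- function(alignment, sequence_id, offset = 0) {
  row <- alignment$mat[.aln_row(alignment, sequence_id), ]
  which(row != "-")
}

.aln_row <- function(alignment, sequence_id) {
  r <- match(sequence_id, alignment$ids)
  if (is.na(r)) stop("sequence '", sequence_id, "' not in alignment")
  r
}

#' Project an interface table onto an alignment
#'
#' Marks the alignment column of every retained interface residue of one
#' partition of an `InterfaceTable`, carrying over its contact degree,
#' tier and ionic/hbond flags. Interface residues that fall outside the
#' sequence range are an error naming them.
#'
#' @param table an `InterfaceTable`.
#' @param alignment an `Alignment`.
#' @param sequence_id alignment row corresponding to the analysed chain.
#' @param side `"a"` or `"b"`: which partition of the table to project.
#' @param offset residue-numbering offset (see [alignment_columns()]).
#' @return data frame, one row per interface residue: residue identity,
#'   `column`, `degree`, `tier`, `ionic`, `hbond`.
#' @export
map_interface_to_alignment <- function(table, alignment, sequence_id,
                                       side = c("a", "b"), offset = 0) {
  side <- match.arg(side)
  deg <- table$residues[table$residues$side == side, , drop = FALSE]
  cols <- alignment_columns(alignment, sequence_id)
  p <- table$pairs
  flag <- function(ch, id) {
    if (side == "a") sel <- p$chain_a == ch & p$res_id_a == id
    else sel <- p$chain_b == ch & p$res_id_b == id
    c(ionic = any(p$ionic[sel]), hbond = any(p$hbond[sel]))
  }
  pos <- deg$res_id - offset
  bad <- pos < 1 | pos > length(cols)
  if (any(bad))
    stop("interface residue(s) beyond sequence range: ",
         paste(residue_label(deg$res_name[bad], deg$res_id[bad]),
               collapse = ", "))
  fl <- t(vapply(seq_len(nrow(deg)),
                 function(r) flag(deg$chain_id[r], deg$res_id[r]),
                 logical(2)))
  aa_row <- alignment$mat[.aln_row(alignment, sequence_id), ]
  out <- data.frame(
    chain_id = deg$chain_id, res_id = deg$res_id,
    res_name = deg$res_name, generic = deg$generic,
    column = cols[pos], aligned_aa = aa_row[cols[pos]],
    degree = deg$degree, tier = deg$tier,
    ionic = fl[, 1], hbond = fl[, 2],
    stringsAsFactors = FALSE)
  # sanity: the aligned letter must match the topology residue when standard
  mism <- !is.na(.AA3TO1[out$res_name]) &
    .AA3TO1[out$res_name] != out$aligned_aa
  if (any(mism))
    warning("alignment letter differs from topology residue at column(s) ",
            paste(out$column[mism], collapse = ", "),
            " (check the numbering offset)")
  out
}

#' Per-column conservation classes against a reference sequence
#'
#' Each non-reference sequence is classified per column: `identical` when
#' the residues match, `similar` when both residues belong to one declared
#' similarity group (by default the single group Arg/Lys), `different`
#' otherwise, and `not_applicable` when either sequence has a gap. Columns
#' where the reference itself is gapped are `not_applicable` throughout.
#'
#' @param alignment an `Alignment`.
#' @param reference_id reference row id.
#' @param similarity_groups list of character vectors of one-letter codes;
#'   default `list(c("R", "K"))`.
#' @return character matrix (non-reference sequences x columns) of classes.
#' @export
conservation_classes <- function(alignment, reference_id,
                                 similarity_groups = list(c("R", "K"))) {
  ref <- alignment$mat[.aln_row(alignment, reference_id), ]
  others <- setdiff(alignment$ids, reference_id)
  valid <- c(LETTERS, "-", "X")
  if (any(!alignment$mat %in% valid))
    stop("unknown residue code(s): ",
         paste(unique(alignment$mat[!alignment$mat %in% valid]),
               collapse = ", "))
  same_group <- function(x, y)
    vapply(seq_along(x), function(i)
      any(vapply(similarity_groups, function(g)
        x[i] %in% g && y[i] %in% g, logical(1))), logical(1))
  out <- matrix(NA_character_, length(others), ncol(alignment$mat),
                dimnames = list(others, NULL))
  for (id in others) {
    s <- alignment$mat[.aln_row(alignment, id), ]
    cls <- ifelse(ref == "-" | s == "-", "not_applicable",
                  ifelse(s == ref, "identical",
                         ifelse(same_group(ref, s), "similar", "different")))
    out[id, ] <- cls
  }
  out
}

#' Compare the interfaces of two homologous complexes on one alignment
#'
#' Labels every alignment column touched by either interface as `shared`,
#' `A_only` or `B_only`, and nominates selectivity candidates: interface
#' columns whose two reference sequences differ (class `different` under
#' the declared similarity groups).
#'
#' @param mapped_a,mapped_b data frames from [map_interface_to_alignment()]
#'   for the two complexes.
#' @param alignment the shared `Alignment`.
#' @param reference_a,reference_b the two reference sequence ids.
#' @param similarity_groups see [conservation_classes()].
#' @return data frame, one row per interface column: `column`, `status`,
#'   residue letters of both references, `class_ab` (conservation class of
#'   reference B against reference A at that column), and
#'   `selectivity_candidate`.
#' @export
compare_complexes <- function(mapped_a, mapped_b, alignment,
                              reference_a, reference_b,
                              similarity_groups = list(c("R", "K"))) {
  if (!nrow(mapped_a) && !nrow(mapped_b)) stop("both interface maps empty")
  cls <- conservation_classes(
    structure(list(ids = c(reference_a, reference_b),
                   mat = alignment$mat[c(.aln_row(alignment, reference_a),
                                         .aln_row(alignment, reference_b)), ,
                                       drop = FALSE]),
              class = "Alignment"),
    reference_a, similarity_groups)[reference_b, ]
  cols <- sort(union(mapped_a$column, mapped_b$column))
  status <- ifelse(cols %in% mapped_a$column & cols %in% mapped_b$column,
                   "shared",
                   ifelse(cols %in% mapped_a$column, "A_only", "B_only"))
  ra <- alignment$mat[.aln_row(alignment, reference_a), cols]
  rb <- alignment$mat[.aln_row(alignment, reference_b), cols]
  data.frame(column = cols, status = status, ref_a = ra, ref_b = rb,
             class_ab = cls[cols],
             selectivity_candidate = cls[cols] == "different",
             stringsAsFactors = FALSE)
}

#' Combined selectivity-determinant report
#'
#' Joins the per-column interface comparison with alanine-scanning results
#' from both complexes. Residues that were not scanned (alanines, glycines,
#' terminal residues) are marked `n.d.`; the interaction type is `polar`
#' when the underlying contact carries an ionic or hydrogen-bond flag and
#' `hydrophobic` otherwise. Output is deterministic: re-running on the same
#' inputs reproduces the file byte for byte.
#'
#' @param comparison data frame from [compare_complexes()].
#' @param mapped_a,mapped_b interface maps from
#'   [map_interface_to_alignment()].
#' @param scan_a,scan_b `AlaScanResult` tables (or `NULL`).
#' @param path output TSV path, or `NULL` to skip writing.
#' @return the report data frame, invisibly when written.
#' @export
selectivity_report <- function(comparison, mapped_a, mapped_b,
                               scan_a = NULL, scan_b = NULL, path = NULL) {
  lookup <- function(mapped, scan, col) {
    r <- match(col, mapped$column)
    if (is.na(r)) return(list(res = "-", ddg = "", itype = ""))
    res <- residue_label(mapped$res_name[r], mapped$res_id[r],
                         mapped$generic[r])
    itype <- if (mapped$ionic[r] || mapped$hbond[r]) "polar" else
      "hydrophobic"
    ddg <- "n.d."
    if (!is.null(scan)) {
      s <- which(scan$chain_id == mapped$chain_id[r] &
                   scan$res_id == mapped$res_id[r])
      if (length(s))
        ddg <- sprintf("%.2f", scan$ddG_mean[s[1]])
    }
    list(res = res, ddg = ddg, itype = itype)
  }
  rows <- lapply(seq_len(nrow(comparison)), function(i) {
    col <- comparison$column[i]
    la <- lookup(mapped_a, scan_a, col)
    lb <- lookup(mapped_b, scan_b, col)
    data.frame(column = col, status = comparison$status[i],
               residue_a = la$res, ddG_a = la$ddg, type_a = la$itype,
               residue_b = lb$res, ddG_b = lb$ddg, type_b = lb$itype,
               conservation = comparison$class_ab[i],
               selectivity_candidate = comparison$selectivity_candidate[i],
               stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(rep_, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(rep_))
  }
  rep_
}
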