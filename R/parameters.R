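#' Load per-atom and bonded force-field parameters into a topology
#'
#' The parameter file is JSON with an `atoms` array and optional `bonds`,
#' `angles` and `dihedrals` arrays. Atom entries are matched against the
#' topology by `(res_name, name)`; `"*"` acts as a wildcard on either field,
#' with more specific entries winning (exact/exact, then `*`/exact, then
#' exact/`*`, then `*`/`*`). Bonded entries are matched by the atom-name
#' tuple of each connectivity record (either orientation), again with `"*"`
#' wildcards.
#'
#' Schema of an atom entry:
#' \preformatted{
#' {"res_name": "LYS", "name": "NZ", "charge": 1.0, "gb_radius": 1.55,
#'  "lj_rmin_half": 1.824, "lj_epsilon": 0.17, "mass": 14.007,
#'  "gb_screen": 0.79}
#' }
#' Bond entries: `{"names": ["CA","CB"], "k": 310.0, "r0": 1.526}`;
#' angle entries: `{"names": ["N","CA","C"], "k": 63.0, "theta0_deg": 110.1}`;
#' dihedral entries: `{"names": ["N","CA","CB","CG"], "pk": 1.4, "n": 3,
#' "delta_deg": 0.0}`.
#'
#' @param path JSON parameter file.
#' @param top a `Topology`.
#' @param strict if `TRUE` (default) an unmatched atom or bonded term is an
#'   error naming the offender; otherwise unmatched atoms keep `NA`
#'   parameters and are reported in a warning.
#' @return the `Topology` with parameter columns and bonded constants filled.
#' @export
load_parameters <- function(path, top, strict = TRUE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(p$atoms)) stop("parameter file has no 'atoms' array: ", path)
  pa <- as.data.frame(p$atoms, stringsAsFactors = FALSE)
  if (any(!is.na(pa$gb_radius) & pa$gb_radius <= 0))
    stop("non-positive gb_radius in parameter file")
  a <- top$atoms

  score <- function(res_match, name_match) 2L * res_match + name_match
  hit <- rep(NA_integer_, nrow(a))
  best <- rep(-1L, nrow(a))
  for (e in seq_len(nrow(pa))) {
    rm_ <- pa$res_name[e] == "*" | pa$res_name[e] == a$res_name
    nm_ <- pa$name[e] == "*" | pa$name[e] == a$name
    cand <- rm_ & nm_
    sc <- score(pa$res_name[e] != "*", pa$name[e] != "*")
    upd <- cand & sc > best
    hit[upd] <- e
    best[upd] <- sc
  }
  unmatched <- which(is.na(hit))
  if (length(unmatched)) {
    who <- paste(a$res_name[unmatched], a$name[unmatched])
    if (strict)
      stop("no parameter entry for atom(s): ",
           paste(unique(who), collapse = ", "))
    warning("unparameterized atom(s): ", paste(unique(who), collapse = ", "))
  }
  take <- function(col) {
    v <- rep(NA_real_, nrow(a))
    if (!is.null(pa[[col]])) v[!is.na(hit)] <- pa[[col]][hit[!is.na(hit)]]
    v
  }
  a$charge <- take("charge")
  a$gb_radius <- take("gb_radius")
  a$lj_rmin_half <- take("lj_rmin_half")
  a$lj_epsilon <- take("lj_epsilon")
  m <- take("mass"); a$mass <- ifelse(is.na(m), a$mass, m)
  s <- take("gb_screen"); a$gb_screen <- ifelse(is.na(s), a$gb_screen, s)
  top$atoms <- a

  top$bonds <- .assign_bonded(top, top$bonds, p$bonds, c("k", "r0"),
                              n_names = 2, strict = strict, kind = "bond")
  top$angles <- .assign_bonded(top, top$angles, p$angles,
                               c("k" = "l_k", "theta0_deg" = "theta0"),
                               n_names = 3, strict = strict, kind = "angle",
                               deg_cols = "theta0_deg")
  top$dihedrals <- .assign_bonded(top, top$dihedrals, p$dihedrals,
                                  c("pk" = "pk", "n" = "n",
                                    "delta_deg" = "delta"),
                                  n_names = 4, strict = strict,
                                  kind = "dihedral", deg_cols = "delta_deg")
  top
}

.assign_bonded <- function(top, terms, entries, cols, n_names, strict, kind,
                           deg_cols = character(0)) {
  if (nrow(terms) == 0) return(terms)
  if (is.null(entries)) {
    if (strict && any(is.na(terms[[if (is.null(names(cols))) cols[1] else
      unname(cols)[1]]])))
      stop("topology has ", kind, " terms but parameter file provides none")
    return(terms)
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  ename <- do.call(rbind, entries$names)
  idx_cols <- c("i", "j", "k", "l")[seq_len(n_names)]
  tnames <- sapply(idx_cols, function(cn) top$atoms$name[terms[[cn]]])
  tnames <- matrix(tnames, ncol = n_names)
  src <- if (is.null(names(cols))) stats::setNames(cols, cols) else {
    nm <- names(cols); nm[nm == ""] <- cols[nm == ""]
    stats::setNames(unname(cols), nm)
  }
  for (t in seq_len(nrow(terms))) {
    fwd <- tnames[t, ]; rev_ <- rev(fwd)
    best <- -1L; hit <- NA_integer_
    for (e in seq_len(nrow(ename))) {
      for (ori in list(fwd, rev_)) {
        ok <- ename[e, ] == "*" | ename[e, ] == ori
        if (all(ok)) {
          sc <- sum(ename[e, ] != "*")
          if (sc > best) { best <- sc; hit <- e }
        }
      }
    }
    if (is.na(hit)) {
      if (strict)
        stop("no ", kind, " parameters for atoms ",
             paste(fwd, collapse = "-"))
      next
    }
    for (sn in names(src)) {
      val <- entries[[sn]][hit]
      if (sn %in% deg_cols) val <- val * pi / 180
      terms[[src[[sn]]]][t] <- val
    }
  }
  terms
}

#' Write a parameter file
#'
#' Inverse of [load_parameters()]: serializes explicit per-entry tables to
#' the documented JSON schema.
#' @param params list with `atoms` and optional `bonds`, `angles`,
#'   `dihedrals` data frames/lists.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a generic-numbering map
#'
#' Three-column TSV (`chain_id`, `res_id`, `generic`) assigning generic
#' residue labels such as Ballesteros-Weinstein numbers (`"6.55"`).
#' @param path TSV file, with header.
#' @return data frame with the three columns.
#' @export
read_generic_number_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character"))
  names(m) <- c("chain_id", "res_id", "generic")
  m
}

#' Annotate topology residues with generic numbers
#'
#' Residues named in the map report both the author number and the generic
#' label in all downstream output (e.g. `"H393^6.55"`). Map rows referring
#' to residues absent from the topology are skipped with a warning; a label
#' used twice within one chain is an error.
#'
#' @param top a `Topology`.
#' @param map data frame from [read_generic_number_map()] (or equivalent).
#' @return the annotated `Topology`.
#' @export
apply_generic_numbers <- function(top, map) {
  if (is.null(map) || nrow(map) == 0) return(top)
  dup <- duplicated(paste(map$chain_id, map$generic))
  if (any(dup))
    stop("generic label collision within a chain: ",
         paste(unique(paste(map$chain_id[dup], map$generic[dup])),
               collapse = ", "))
  a <- top$atoms
  for (r in seq_len(nrow(map))) {
    sel <- a$chain_id == map$chain_id[r] & a$res_id == map$res_id[r]
    if (!any(sel)) {
      warning("generic-number map entry (", map$chain_id[r], ", ",
              map$res_id[r], ") matches no residue; skipped")
      next
    }
    a$generic[sel] <- map$generic[r]
  }
  top$atoms <- a
  top
}
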