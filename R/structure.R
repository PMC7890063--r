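#' Parse a protein structure from PDB text
#'
#' Reads ATOM/HETATM records (first MODEL only, via [bio3d::read.pdb()]),
#' partitions atoms into polymer and hetero groups, collapses alternate
#' locations to the highest-occupancy conformer (ties broken by the first
#' alt-loc label), folds HETATM records of standard residues (e.g.
#' selenomethionine MSE) into the polymer, and derives a one-letter sequence
#' per chain. Unknown residue codes become `X` with a warning.
#'
#' @param text PDB-format content as a single string or character vector of
#'   lines.
#' @param id Structure identifier stored in the model.
#' @return An object of class `structure_model` with elements:
#'   \describe{
#'     \item{id}{identifier}
#'     \item{atoms}{data frame of polymer atoms}
#'     \item{hetero_atoms}{data frame of hetero (ligand candidate) atoms}
#'     \item{residues}{data frame of polymer residues: `chain`, `resno`,
#'       `insert`, `resid`, `aa`, `seq_pos` (1-based index within its chain)}
#'     \item{chains}{named character vector, one-letter sequence per chain}
#'   }
#' @export
parse_structure <- function(text, id = "structure") {
  if (is.character(text) && length(text) > 1) text <- paste(text, collapse = "\n")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf)
  read_structure(tf, id = id)
}

#' @rdname parse_structure
#' @param path Path to a PDB file.
#' @export
read_structure <- function(path, id = sub("\\.(pdb|ent)$", "", basename(path))) {
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, "ATOM")))
    stop("malformed input: no ATOM records in ", id)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    infer_element(at$elety[is.na(at$elesy) | at$elesy == ""])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, alt = at$alt,
    resid = at$resid, chain = at$chain, resno = at$resno,
    insert = at$insert, x = at$x, y = at$y, z = at$z,
    occupancy = at$o, element = toupper(at$elesy),
    hetero = at$type == "HETATM" & !(at$resid %in% STANDARD_AA3),
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- "A"
  atoms <- collapse_altloc(atoms)

  poly <- atoms[!atoms$hetero, , drop = FALSE]
  het <- atoms[atoms$hetero, , drop = FALSE]
  residues <- unique(poly[order(poly$chain, poly$resno, poly$insert),
                          c("chain", "resno", "insert", "resid")])
  rownames(residues) <- NULL
  aa <- suppressWarnings(bio3d::aa321(residues$resid))
  if (any(aa == "X" & !(residues$resid %in% "UNK")))
    warning("unknown residue code(s) mapped to X: ",
            paste(unique(residues$resid[aa == "X"]), collapse = ", "))
  residues$aa <- aa
  residues$seq_pos <- stats::ave(seq_len(nrow(residues)), residues$chain,
                                 FUN = seq_along)
  chains <- vapply(split(residues, residues$chain),
                   function(r) paste(r$aa[order(r$seq_pos)], collapse = ""),
                   character(1))
  structure(
    list(id = id, atoms = poly, hetero_atoms = het,
         residues = residues, chains = chains),
    class = "structure_model"
  )
}

# crude element inference from the atom name when the element column is blank
infer_element <- function(name) {
  el <- sub("[0-9'*]+.*$", "", sub("^[0-9]+", "", trimws(name)))
  substr(toupper(el), 1, ifelse(toupper(el) %in% c("FE", "MG", "MN", "ZN",
                                                   "NA", "CL", "SE", "BR"),
                                2, 1))
}

collapse_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, atoms$resid,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- atoms[idx, ]
    best <- idx[order(-sub$occupancy, sub$alt)][1]
    best
  }), use.names = FALSE)
  out <- atoms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure %s: %d polymer residues in %d chain(s), %d hetero group(s)\n",
              x$id, nrow(x$residues), length(x$chains),
              length(unique(hetero_key(x$hetero_atoms)))))
  invisible(x)
}

hetero_key <- function(het) {
  if (!nrow(het)) return(character(0))
  paste(het$resid, het$chain, het$resno, het$insert, sep = "/")
}

# solvent and monatomic-ion codes dropped from ligand selection by default;
# MG/MN are catalytic cofactors, excluded but whitelistable via `include`
DEFAULT_LIGAND_EXCLUDE <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "ZN",
                            "MG", "MN", "CA")

#' Select ligand groups from a structure
#'
#' Default behaviour keeps every hetero group except waters and monatomic
#' ions (including the catalytic Mg2+/Mn2+, which can be whitelisted through
#' `include` since they are cofactors rather than the substrate). With
#' `include`, exactly those residue codes are selected. Groups are ranked by
#' heavy-atom count, largest first.
#'
#' @param model A `structure_model`.
#' @param include Optional character vector of residue codes to select
#'   exactly (overrides the exclusion list).
#' @param exclude Optional character vector of residue codes to drop,
#'   replacing the default exclusion list.
#' @return An object of class `ligand_selection` with `structure_id`,
#'   `groups` (data frame: code, chain, resno, insert, n_heavy_atoms) and
#'   `atoms` (flattened heavy-atom data frame).
#' @export
select_ligands <- function(model, include = NULL, exclude = NULL) {
  stopifnot(inherits(model, "structure_model"))
  het <- model$hetero_atoms
  het <- het[het$element != "H" & het$element != "D", , drop = FALSE]
  if (!is.null(include)) {
    sel <- het[het$resid %in% toupper(include), , drop = FALSE]
    if (!nrow(sel))
      stop("no hetero groups with code(s) ",
           paste(include, collapse = ", "), " in ", model$id)
  } else {
    excl <- toupper(exclude %||% DEFAULT_LIGAND_EXCLUDE)
    sel <- het[!(het$resid %in% excl), , drop = FALSE]
    if (!nrow(sel)) {
      dropped <- unique(het$resid)
      stop("no ligand left after excluding ",
           paste(dropped, collapse = ", "), " in ", model$id)
    }
  }
  key <- paste(sel$resid, sel$chain, sel$resno, sel$insert, sep = "\r")
  groups <- unique(data.frame(code = sel$resid, chain = sel$chain,
                              resno = sel$resno, insert = sel$insert,
                              key = key, stringsAsFactors = FALSE))
  groups$n_heavy_atoms <- as.integer(table(key)[groups$key])
  groups <- groups[order(-groups$n_heavy_atoms, groups$key),
                   setdiff(names(groups), "key")]
  rownames(groups) <- NULL
  structure(
    list(structure_id = model$id, groups = groups, atoms = sel),
    class = "ligand_selection"
  )
}

#' @export
print.ligand_selection <- function(x, ...) {
  cat(sprintf("Ligand selection for %s: %d group(s)\n", x$structure_id,
              nrow(x$groups)))
  print(x$groups)
  invisible(x)
}

#' Extract the ligand-proximal (active-site) pocket
#'
#' A polymer residue belongs to the pocket iff the minimum Euclidean distance
#' between any of its heavy atoms and any ligand heavy atom is less than or
#' equal to `cutoff` (the 6.0 A convention for terpene-synthase binding
#' pockets). Hydrogens are ignored. By default the pocket is restricted to
#' the chain contributing the most pocket residues; set `span_chains = TRUE`
#' to keep all chains.
#'
#' @param model A `structure_model`.
#' @param ligands A `ligand_selection` from [select_ligands()].
#' @param cutoff Distance cutoff in Angstroms (default 6.0, inclusive).
#' @param span_chains Keep pocket residues from every chain?
#' @return An object of class `pocket` with `structure_id`, `cutoff`, and a
#'   `residues` data frame (`chain`, `resno`, `insert`, `resid`, `aa`,
#'   `seq_pos`, `min_dist`) ordered by (chain, resno, insert).
#' @export
extract_pocket <- function(model, ligands, cutoff = 6.0, span_chains = FALSE) {
  stopifnot(inherits(model, "structure_model"),
            inherits(ligands, "ligand_selection"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("`cutoff` must be > 0")
  lig <- ligands$atoms
  if (!nrow(lig)) stop("empty ligand selection")
  poly <- model$atoms
  poly <- poly[poly$element != "H" & poly$element != "D", , drop = FALSE]
  md <- min_dist_to_set(as.matrix(poly[, c("x", "y", "z")]),
                        as.matrix(lig[, c("x", "y", "z")]))
  poly$min_dist <- md
  key <- paste(poly$chain, poly$resno, poly$insert, sep = "\r")
  res_min <- tapply(poly$min_dist, key, min)
  res <- model$residues
  rkey <- paste(res$chain, res$resno, res$insert, sep = "\r")
  res$min_dist <- as.numeric(res_min[rkey])
  hit <- res[!is.na(res$min_dist) & res$min_dist <= cutoff, , drop = FALSE]
  if (nrow(hit) && !span_chains) {
    tab <- sort(table(hit$chain), decreasing = TRUE)
    hit <- hit[hit$chain == names(tab)[1], , drop = FALSE]
  }
  hit <- hit[order(hit$chain, hit$resno, hit$insert), , drop = FALSE]
  rownames(hit) <- NULL
  structure(
    list(structure_id = model$id, cutoff = cutoff, residues = hit),
    class = "pocket"
  )
}

# row-wise minimum distance from points P to point set L
min_dist_to_set <- function(P, L) {
  if (!nrow(P)) return(numeric(0))
  pn <- rowSums(P^2)
  ln <- rowSums(L^2)
  d2 <- outer(pn, ln, "+") - 2 * P %*% t(L)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("Pocket of %s at %.1f A: %d residue(s)\n",
              x$structure_id, x$cutoff, nrow(x$residues)))
  if (nrow(x$residues))
    cat(" ", paste0(x$residues$aa, x$residues$resno, collapse = " "), "\n")
  invisible(x)
}

#' Physicochemical environment of a pocket
#'
#' Labels every pocket residue hydrophobic / polar / negative / positive from
#' a fixed residue-class table (the colouring convention used for binding
#' pocket surfaces) and tallies the classes.
#'
#' @param pocket A `pocket` from [extract_pocket()].
#' @return A list with `classes` (named character vector, one label per
#'   pocket residue; unrecognised residues are `"unknown"`) and `counts`.
#' @export
pocket_environment <- function(pocket) {
  stopifnot(inherits(pocket, "pocket"))
  if (!nrow(pocket$residues)) stop("pocket is empty")
  aa <- pocket$residues$aa
  cls <- unname(RESIDUE_CLASS[aa])
  cls[is.na(cls)] <- "unknown"
  names(cls) <- paste0(aa, pocket$residues$resno)
  counts <- table(factor(cls, levels = c("hydrophobic", "polar", "negative",
                                         "positive", "unknown")))
  list(classes = cls, counts = counts[counts > 0 | names(counts) != "unknown"])
}

#' Write a pocket report as TSV
#'
#' Columns: structure_id, chain, resseq, icode, resname, aa, seq_pos,
#' min_distance_A, class.
#'
#' @param pocket A `pocket`.
#' @param path Output path.
#' @export
write_pocket_tsv <- function(pocket, path) {
  r <- pocket$residues
  cls <- unname(RESIDUE_CLASS[r$aa])
  cls[is.na(cls)] <- "unknown"
  df <- data.frame(
    structure_id = pocket$structure_id, chain = r$chain, resseq = r$resno,
    icode = r$insert, resname = r$resid, aa = r$aa, seq_pos = r$seq_pos,
    min_distance_A = round(r$min_dist, 3), class = cls
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
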