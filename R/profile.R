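round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Build a unified active-site template from one or more pockets
#'
#' With a single template the active-site positions are simply the pocket's
#' sequence positions. With several, every further template's pocket
#' positions are mapped onto the first template through their global pairwise
#' alignment: positions landing on an existing position are merged (sources
#' recorded), positions landing elsewhere on template 1 are added in template
#' 1 coordinates, and positions aligned to a gap in template 1 are appended
#' anchored on their own template. The result is the cross-template union
#' that defines the profile columns.
#'
#' @param pockets List of `pocket` objects (one per template, first is the
#'   anchor).
#' @param sequences Character vector of template chain sequences, parallel to
#'   `pockets` (the chain the pocket was extracted from).
#' @param ids Template identifiers; defaults to the pockets' structure ids.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `active_site_template` with `template_ids`,
#'   `template_seqs`, and `positions` (data frame: `anchor` template index,
#'   `pos` 1-based sequence position in the anchor, `residue` anchor-template
#'   letter, `sources`).
#' @export
build_template <- function(pockets, sequences, ids = NULL,
                           scheme = scoring_scheme()) {
  if (inherits(pockets, "pocket")) pockets <- list(pockets)
  stopifnot(length(pockets) >= 1, length(sequences) == length(pockets))
  ids <- ids %||% vapply(pockets, function(p) p$structure_id, character(1))
  sequences <- vapply(sequences, check_aa_sequence, character(1),
                      USE.NAMES = FALSE)
  p1 <- sort(unique(pockets[[1]]$residues$seq_pos))
  pos <- data.frame(
    anchor = 1L, pos = p1,
    residue = substring(sequences[1], p1, p1),
    sources = ids[1], stringsAsFactors = FALSE
  )
  for (t in seq_along(pockets)[-1]) {
    aln <- global_align(sequences[t], sequences[1], scheme, ids[t], ids[1])
    if (percent_identity(aln) < 10)
      warning(sprintf("templates %s and %s align at <10%% identity; union may be unreliable",
                      ids[t], ids[1]))
    cm <- aln$column_map
    for (p in sort(unique(pockets[[t]]$residues$seq_pos))) {
      col <- which(!is.na(cm$query_pos) & cm$query_pos == p)
      t1pos <- cm$target_pos[col]
      if (!is.na(t1pos)) {
        hit <- which(pos$anchor == 1L & pos$pos == t1pos)
        if (length(hit)) {
          pos$sources[hit] <- paste(pos$sources[hit], ids[t], sep = "+")
        } else {
          pos <- rbind(pos, data.frame(
            anchor = 1L, pos = t1pos,
            residue = substring(sequences[1], t1pos, t1pos),
            sources = ids[t], stringsAsFactors = FALSE
          ))
        }
      } else {
        pos <- rbind(pos, data.frame(
          anchor = t, pos = p,
          residue = substring(sequences[t], p, p),
          sources = ids[t], stringsAsFactors = FALSE
        ))
      }
    }
  }
  pos <- pos[order(pos$anchor, pos$pos), , drop = FALSE]
  rownames(pos) <- NULL
  structure(
    list(template_ids = ids, template_seqs = sequences, positions = pos),
    class = "active_site_template"
  )
}

#' @export
print.active_site_template <- function(x, ...) {
  cat(sprintf("Active-site template (%s): %d position(s)\n",
              paste(x$template_ids, collapse = " + "), nrow(x$positions)))
  invisible(x)
}

template_signature <- function(tmpl) {
  paste(paste(tmpl$template_ids, collapse = "+"), nrow(tmpl$positions),
        sep = ":")
}

#' Project an active-site template onto a query sequence
#'
#' Aligns the query globally to each anchor template sequence and reads off,
#' for every template position, the query residue aligned to it (`-` where
#' the query has a gap). A query equal to a template sequence round-trips to
#' that template's pocket residues.
#'
#' @param query Query amino-acid sequence.
#' @param tmpl An `active_site_template`.
#' @param scheme A [scoring_scheme()].
#' @param query_id Label for the query.
#' @return An object of class `active_site_profile` with `enzyme_id`,
#'   `residues` (string over the 20 amino acids + `-`, one character per
#'   template position) and the template signature.
#' @export
project_profile <- function(query, tmpl, scheme = scoring_scheme(),
                            query_id = "query") {
  stopifnot(inherits(tmpl, "active_site_template"))
  query <- check_aa_sequence(query, "`query`")
  chars <- character(nrow(tmpl$positions))
  for (a in unique(tmpl$positions$anchor)) {
    aln <- global_align(query, tmpl$template_seqs[a], scheme,
                        query_id, tmpl$template_ids[a])
    cm <- aln$column_map
    # template position -> query residue (or "-") lookup
    qchar <- rep("-", nchar(tmpl$template_seqs[a]))
    ok <- !is.na(cm$target_pos)
    qchar[cm$target_pos[ok]] <- ifelse(
      is.na(cm$query_pos[ok]), "-",
      substring(query, cm$query_pos[ok], cm$query_pos[ok])
    )
    rows <- which(tmpl$positions$anchor == a)
    chars[rows] <- qchar[tmpl$positions$pos[rows]]
  }
  structure(
    list(enzyme_id = query_id, residues = paste(chars, collapse = ""),
         template = template_signature(tmpl)),
    class = "active_site_profile"
  )
}

#' @export
print.active_site_profile <- function(x, ...) {
  cat(sprintf("Active-site profile %s [%s]: %s\n", x$enzyme_id, x$template,
              x$residues))
  invisible(x)
}

#' Active-site identity between two profiles
#'
#' Positions where both profiles carry a residue (no gap) are comparable;
#' identity is 100 x identical / comparable. The percentage over the full
#' template length (fixed denominator, gaps counting as mismatches) is also
#' reported, and reported percentages are additionally rounded half-up to
#' integers for display, matching the "95% (36/38)" convention.
#'
#' @param a,b `active_site_profile` objects built on the same template.
#' @return A list with `identical_count`, `comparable_count`, `n_positions`,
#'   `percentage` (raw, comparable denominator), `percentage_rounded`, and
#'   `percentage_full_denominator`.
#' @export
profile_identity <- function(a, b) {
  stopifnot(inherits(a, "active_site_profile"),
            inherits(b, "active_site_profile"))
  if (!identical(a$template, b$template))
    stop("incompatible profiles: built on different active-site templates")
  ca <- strsplit(a$residues, "")[[1]]
  cb <- strsplit(b$residues, "")[[1]]
  comparable <- ca != "-" & cb != "-"
  identical_n <- sum(comparable & ca == cb)
  pct <- if (sum(comparable)) 100 * identical_n / sum(comparable) else NaN
  list(
    identical_count = identical_n,
    comparable_count = sum(comparable),
    n_positions = length(ca),
    percentage = pct,
    percentage_rounded = round_half_up(pct),
    percentage_full_denominator = 100 * identical_n / length(ca)
  )
}

# motif patterns of class I terpene synthases:
# aspartate-rich D(D/E)XXD and the NSE triad (N/D)Dxx(S/T)xxxE
MOTIFS <- list(
  aspartate_rich = list(regex = "^D[DE][A-Z]{2}D$", width = 5L),
  nse_triad = list(regex = "^[ND]D[A-Z]{2}[ST][A-Z]{3}E$", width = 9L)
)

#' Scan a sequence for terpene-synthase catalytic motifs
#'
#' Finds every start position (overlap allowed) of the aspartate-rich motif
#' D(D/E)XXD and of the NSE triad (N/D)Dxx(S/T)xxxE. A sequence is
#' "complete" when it carries at least one hit of each motif; incomplete
#' pockets (e.g. a missing NSE triad) disqualify a candidate downstream.
#'
#' @param seq Amino-acid sequence.
#' @return A data frame with columns `motif`, `start` (1-based) and `match`,
#'   with attribute `complete` (logical).
#' @seealso [motif_complete()]
#' @export
scan_motifs <- function(seq) {
  seq <- check_aa_sequence(seq)
  hits <- lapply(names(MOTIFS), function(m) {
    w <- MOTIFS[[m]]$width
    n <- nchar(seq)
    if (n < w)
      return(data.frame(motif = character(0), start = integer(0),
                        match = character(0)))
    starts <- seq_len(n - w + 1L)
    windows <- substring(seq, starts, starts + w - 1L)
    ok <- grepl(MOTIFS[[m]]$regex, windows)
    data.frame(motif = rep(m, sum(ok)), start = starts[ok],
               match = windows[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  attr(out, "complete") <- all(vapply(names(MOTIFS),
                                      function(m) any(out$motif == m),
                                      logical(1)))
  out
}

#' @rdname scan_motifs
#' @return `motif_complete` returns a single logical.
#' @export
motif_complete <- function(seq) {
  attr(scan_motifs(seq), "complete")
}

#' Predict enzyme function from active-site identity
#'
#' Each query is compared against experimentally characterized reference
#' enzymes on the shared active-site template. A query inherits the label of
#' its highest-active-site-identity reference when that identity reaches the
#' active-site threshold AND the query carries both catalytic motifs;
#' otherwise it is reported "unassigned" with the reason. Ties report all
#' tied references.
#'
#' @param queries Named character vector of query sequences.
#' @param references Data frame with columns `id`, `sequence`, `label`
#'   (experimental annotations, free strings).
#' @param tmpl An `active_site_template`.
#' @param scheme A [scoring_scheme()].
#' @param thresholds Named numeric vector with `full_seq` (the ">50% identity
#'   = high similarity" convention, reported as a flag) and `active_site`
#'   (the ">90% active-site identity" call threshold), in percent.
#' @return A data frame of class `function_calls` with one row per query:
#'   `enzyme_id`, `nearest_reference`, `reference_label`,
#'   `active_site_identity`, `full_sequence_identity`,
#'   `high_full_seq_similarity`, `motif_complete`, `predicted_label`,
#'   `evidence`.
#' @export
predict_function <- function(queries, references, tmpl,
                             scheme = scoring_scheme(),
                             thresholds = c(full_seq = 50, active_site = 90)) {
  stopifnot(inherits(tmpl, "active_site_template"),
            is.data.frame(references),
            all(c("id", "sequence", "label") %in% names(references)))
  if (!nrow(references)) stop("no references given")
  if (is.null(names(queries)) || any(names(queries) == ""))
    stop("queries must be named")
  ref_profiles <- lapply(seq_len(nrow(references)), function(i)
    project_profile(references$sequence[i], tmpl, scheme, references$id[i]))
  rows <- lapply(names(queries), function(qid) {
    qp <- project_profile(queries[[qid]], tmpl, scheme, qid)
    as_id <- vapply(ref_profiles,
                    function(rp) profile_identity(qp, rp)$percentage,
                    numeric(1))
    best <- max(as_id)
    tied <- which(as_id >= best - 1e-9)
    best_ids <- references$id[tied]
    best_labels <- unique(references$label[tied])
    full_id <- percent_identity(
      global_align(queries[[qid]], references$sequence[tied[1]], scheme))
    complete <- motif_complete(queries[[qid]])
    missing <- setdiff(names(MOTIFS),
                       unique(scan_motifs(queries[[qid]])$motif))
    assigned <- is.finite(best) && best >= thresholds[["active_site"]] &&
      complete
    evidence <- c(
      sprintf("active-site identity %.1f%% vs %s",
              best, paste(best_ids, collapse = ",")),
      if (!complete) sprintf("incomplete pocket (missing %s)",
                             paste(gsub("_", " ", missing), collapse = ", ")),
      if (is.finite(best) && best < thresholds[["active_site"]])
        sprintf("below active-site threshold %g%%",
                thresholds[["active_site"]])
    )
    data.frame(
      enzyme_id = qid,
      nearest_reference = paste(best_ids, collapse = ";"),
      reference_label = paste(best_labels, collapse = ";"),
      active_site_identity = best,
      full_sequence_identity = full_id,
      high_full_seq_similarity = full_id > thresholds[["full_seq"]],
      motif_complete = complete,
      predicted_label = if (assigned) paste(best_labels, collapse = ";")
                        else "unassigned",
      evidence = paste(evidence, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("function_calls", "data.frame")
  out
}

#' Write active-site profiles as aligned FASTA
#'
#' One row per enzyme over the template positions (gaps as `-`), loadable by
#' any alignment viewer.
#'
#' @param profiles List of `active_site_profile` objects.
#' @param path Output path.
#' @export
write_profiles_fasta <- function(profiles, path) {
  seqs <- setNames(
    vapply(profiles, function(p) p$residues, character(1)),
    vapply(profiles, function(p) p$enzyme_id, character(1))
  )
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}
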