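#' Define an amplicon panel
#'
#' A panel is an ordered list of amplicons; each amplicon covers one or more
#' exon sub-intervals (segments). Coordinates are 0-based half-open and
#' exon-relative on the coding strand. A segment with `end = NA` runs to the
#' exon end; `trim_end` clips that many bases from the 3' end of the exon
#' (used when a primer sits inside the exon).
#'
#' @param amplicons list of amplicon definitions, each a `list(name =,
#'   segments = data.frame(exon, start, end, trim_end))`.
#' @param name panel label.
#' @return An object of class `amplicon_panel`.
#' @seealso [default_panel()]
#' @export
amplicon_panel <- function(amplicons, name = "custom") {
  nms <- vapply(amplicons, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate amplicon names")
  for (a in amplicons) {
    seg <- a$segments
    stopifnot(is.data.frame(seg), nrow(seg) >= 1L,
              all(c("exon", "start") %in% names(seg)))
    if (is.null(seg$end)) seg$end <- NA_integer_
    if (is.null(seg$trim_end)) seg$trim_end <- 0L
    if (is.unsorted(seg$exon, strictly = TRUE)) {
      stop("segment exon indices must be strictly increasing in amplicon ", a$name)
    }
  }
  amplicons <- lapply(amplicons, function(a) {
    seg <- a$segments
    if (is.null(seg$end)) seg$end <- NA_integer_
    if (is.null(seg$trim_end)) seg$trim_end <- 0L
    seg$exon <- as.integer(seg$exon)
    seg$start <- as.integer(seg$start)
    seg$end <- as.integer(seg$end)
    seg$trim_end <- as.integer(seg$trim_end)
    list(name = a$name, segments = seg[, c("exon", "start", "end", "trim_end")])
  })
  structure(list(name = name, amplicons = amplicons), class = "amplicon_panel")
}

#' The default three-amplicon MICA/MICB panel
#'
#' Exons 2 and 3 are covered completely by separate amplicons; exons 4 and 5
#' are amplified as one joined amplicon with primers inside the exons, so
#' the first 65 bases of exon 4 and the last 13 bases of exon 5 are not
#' covered. Exons 1 and 6 are not part of the assay.
#'
#' @return An [amplicon_panel()].
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  amplicon_panel(list(
    list(name = "ex2", segments = data.frame(exon = 2L, start = 0L)),
    list(name = "ex3", segments = data.frame(exon = 3L, start = 0L)),
    list(name = "ex4-5", segments = data.frame(
      exon = c(4L, 5L), start = c(65L, 0L),
      end = NA_integer_, trim_end = c(0L, 13L)))
  ), name = "mic-ex2-ex5")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("amplicon_panel '%s' (%d amplicons)\n", x$name, length(x$amplicons)))
  for (a in x$amplicons) {
    seg <- a$segments
    cat(sprintf("  %-6s %s\n", a$name, paste(sprintf(
      "exon%d[%d:%s%s]", seg$exon, seg$start,
      ifelse(is.na(seg$end), "len", seg$end),
      ifelse(seg$trim_end > 0, sprintf("-%d", seg$trim_end), "")), collapse = " + ")))
  }
  invisible(x)
}

#' Amplicon names of a panel, in panel order
#' @param panel an [amplicon_panel()].
#' @return Character vector of amplicon names.
#' @export
panel_amplicon_names <- function(panel) {
  vapply(panel$amplicons, `[[`, "", "name")
}

#' Read/write a panel configuration (YAML)
#'
#' @param path YAML file. The format mirrors the panel structure: a `name`
#'   and a list of `amplicons` with `name` and `segments` entries.
#' @return [read_panel()] returns an [amplicon_panel()]; [write_panel()]
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  y <- yaml::read_yaml(path)
  amplicon_panel(lapply(y$amplicons, function(a) {
    seg <- do.call(rbind, lapply(a$segments, function(s) {
      data.frame(exon = s$exon, start = s$start,
                 end = if (is.null(s$end)) NA_integer_ else s$end,
                 trim_end = if (is.null(s$trim_end)) 0L else s$trim_end)
    }))
    list(name = a$name, segments = seg)
  }), name = if (is.null(y$name)) "custom" else y$name)
}

#' @rdname read_panel
#' @param panel an [amplicon_panel()].
#' @export
write_panel <- function(panel, path) {
  y <- list(name = panel$name, amplicons = lapply(panel$amplicons, function(a) {
    list(name = a$name, segments = lapply(seq_len(nrow(a$segments)), function(i) {
      s <- as.list(a$segments[i, ])
      if (is.na(s$end)) s$end <- NULL
      if (identical(s$trim_end, 0L)) s$trim_end <- NULL
      s
    }))
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Project one allele onto a panel
#'
#' Restricts an allele's exon sequences to the panel's covered intervals.
#' The per-amplicon projected sequences (the allele's *signature*) are the
#' unit of all matching: two alleles identical on every projection cannot be
#' distinguished by the assay.
#'
#' @param allele a single-row slice of an [allele_db()] (or a list with
#'   `allele` and `exon1`..`exon6` entries).
#' @param panel an [amplicon_panel()].
#' @return Named character vector, one projected sequence per amplicon.
#' @examples
#' db <- allele_db(data.frame(gene = "MICA", allele = "MICA*001",
#'   exon2 = strrep("A", 20), exon3 = strrep("C", 20),
#'   exon4 = strrep("G", 70), exon5 = strrep("T", 20)))
#' project_allele(db[1, ], default_panel())
#' @export
project_allele <- function(allele, panel) {
  al <- as.list(allele)
  out <- setNames(character(length(panel$amplicons)), panel_amplicon_names(panel))
  for (a in panel$amplicons) {
    seg <- a$segments
    parts <- character(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      seq <- al[[paste0("exon", seg$exon[i])]]
      if (is.null(seq) || is.na(seq)) {
        stop(structure(class = c("micatype_projection_error", "error", "condition"),
                       list(message = sprintf("allele %s lacks exon %d required by amplicon %s",
                                              al$allele, seg$exon[i], a$name),
                            call = NULL)))
      }
      L <- nchar(seq)
      s <- seg$start[i]
      e <- if (is.na(seg$end[i])) L else seg$end[i]
      e <- e - seg$trim_end[i]
      if (!(s >= 0L && s < e && e <= L)) {
        stop(structure(class = c("micatype_projection_error", "error", "condition"),
                       list(message = sprintf(
                         "invalid interval [%d,%d) for exon %d (length %d) of allele %s",
                         s, e, seg$exon[i], L, al$allele), call = NULL)))
      }
      parts[i] <- substr(seq, s + 1L, e)
    }
    out[a$name] <- paste(parts, collapse = "")
  }
  out
}

#' Project all alleles of a database onto a panel
#'
#' @param db an [allele_db()].
#' @param panel an [amplicon_panel()].
#' @param on_error `"error"` to fail on alleles missing a required exon,
#'   `"drop"` to exclude them with a warning (they cannot be matched).
#' @return data.frame: `gene`, `allele`, `first_field`, then one character
#'   column per amplicon (named as in the panel).
#' @export
allele_signatures <- function(db, panel, on_error = c("error", "drop")) {
  on_error <- match.arg(on_error)
  amps <- panel_amplicon_names(panel)
  rows <- vector("list", nrow(db))
  keep <- logical(nrow(db))
  for (i in seq_len(nrow(db))) {
    sig <- tryCatch(project_allele(db[i, ], panel),
                    micatype_projection_error = function(e) e)
    if (inherits(sig, "error")) {
      if (on_error == "error") stop(sig)
      warning("excluded from matching: ", conditionMessage(sig), call. = FALSE)
    } else {
      rows[[i]] <- sig
      keep[i] <- TRUE
    }
  }
  sigmat <- do.call(rbind, rows[keep])
  out <- data.frame(gene = db$gene[keep], allele = db$allele[keep],
                    first_field = db$first_field[keep], stringsAsFactors = FALSE)
  for (a in amps) out[[a]] <- unname(sigmat[, a])
  out
}

sig_key <- function(sigs, amps) {
  do.call(paste, c(unname(as.list(sigs[amps])), list(sep = "\r")))
}

#' Ambiguity groups induced by a panel
#'
#' Two protein-level (first-field) allele groups fall into the same
#' ambiguity group when the panel cannot tell them apart: some allele of one
#' shares an identical signature (all amplicons) with some allele of the
#' other. Groups are merged transitively. A group with more than one member
#' is displayed as its representative name plus `#` (e.g. `MICB*005#`).
#'
#' The default representative is the smallest member by [allele_name_order()];
#' `representative_override` (named character: default representative ->
#' desired member) covers reporting conventions where another member is the
#' customary name.
#'
#' @param db an [allele_db()].
#' @param panel an [amplicon_panel()].
#' @param representative_override named character vector, or `NULL`.
#' @param on_error passed to [allele_signatures()].
#' @return data.frame per group: `gene`, `representative`, `display`,
#'   `members` (comma-joined first fields), `n_members`; sorted by
#'   representative. Attribute `display_map` maps first field -> display.
#' @export
ambiguity_groups <- function(db, panel, representative_override = NULL,
                             on_error = "error") {
  sigs <- allele_signatures(db, panel, on_error = on_error)
  amps <- panel_amplicon_names(panel)
  key <- sig_key(sigs, amps)
  out <- list()
  for (g in db_genes(db)) {
    idx <- sigs$gene == g
    ff <- sigs$first_field[idx]
    uff <- sort_allele_names(unique(ff))
    parent <- seq_along(uff)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union_ <- function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    }
    for (k in split(match(ff, uff), key[idx])) {
      k <- unique(k)
      if (length(k) > 1L) for (j in k[-1L]) union_(k[1L], j)
    }
    roots <- vapply(seq_along(uff), find, 1L)
    for (r in unique(roots)) {
      members <- uff[roots == r]
      rep_name <- members[1L]
      if (!is.null(representative_override) && rep_name %in% names(representative_override)) {
        cand <- representative_override[[rep_name]]
        if (!cand %in% members) {
          stop("representative_override target ", cand, " is not a member of its group")
        }
        rep_name <- cand
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, representative = rep_name,
        display = paste0(rep_name, if (length(members) > 1L) "#" else ""),
        members = paste(members, collapse = ","),
        n_members = length(members), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[allele_name_order(res$representative), , drop = FALSE]
  rownames(res) <- NULL
  dm <- unlist(lapply(seq_len(nrow(res)), function(i) {
    mem <- strsplit(res$members[i], ",", fixed = TRUE)[[1L]]
    setNames(rep(res$display[i], length(mem)), mem)
  }))
  attr(res, "display_map") <- dm
  res
}

#' Map first-field names to ambiguity-group display names
#' @param groups result of [ambiguity_groups()].
#' @return Named character vector (first field -> display).
#' @export
group_display_map <- function(groups) attr(groups, "display_map")

#' Check that no amplicon sequence is shared between genes
#'
#' Gene assignment of reads relies on every projected amplicon sequence
#' being unique to one gene. This audit lists any projection shared between
#' genes; an empty report means the genes are separable.
#'
#' @param db a two-gene [allele_db()].
#' @param panel an [amplicon_panel()].
#' @return data.frame with columns `amplicon`, `sequence`, `alleles_a`,
#'   `alleles_b` (comma-joined); zero rows when the genes are disjoint.
#'   Attribute `disjoint` is `TRUE`/`FALSE`.
#' @export
cross_gene_disjointness <- function(db, panel) {
  genes <- db_genes(db)
  if (length(genes) != 2L) stop("cross-gene check requires a two-gene database")
  sigs <- allele_signatures(db, panel, on_error = "drop")
  rows <- list()
  for (a in panel_amplicon_names(panel)) {
    sa <- sigs[sigs$gene == genes[1L], ]
    sb <- sigs[sigs$gene == genes[2L], ]
    shared <- intersect(sa[[a]], sb[[a]])
    for (s in shared) {
      rows[[length(rows) + 1L]] <- data.frame(
        amplicon = a, sequence = s,
        alleles_a = paste(sa$allele[sa[[a]] == s], collapse = ","),
        alleles_b = paste(sb$allele[sb[[a]] == s], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(amplicon = character(0), sequence = character(0),
               alleles_a = character(0), alleles_b = character(0))
  attr(rep, "disjoint") <- nrow(rep) == 0L
  rep
}
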