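EXON_COLS <- paste0("exon", 1:6)

#' Construct an allele database
#'
#' An allele database holds per-exon nucleotide sequences for named alleles
#' of one or two MIC genes. Exons 2 and 3 are mandatory for every allele
#' because the assay amplifies them; exons 1 and 6 may be present (they are
#' needed to represent alleles distinguishable only outside the covered
#' regions) but are never used for matching.
#'
#' @param alleles data.frame with columns `gene`, `allele` and `exon1` ..
#'   `exon6` (character; `NA` for absent exons).
#' @param release free-text version label for the database.
#' @return An object of class `allele_db`: the validated data.frame plus a
#'   `first_field` column, with attributes `release` and `genes`.
#' @examples
#' db <- allele_db(data.frame(
#'   gene = "MICA", allele = c("MICA*001", "MICA*002"),
#'   exon2 = c("ACGTACGT", "ACGTACGA"), exon3 = c("GGGGCCCC", "GGGGCCCC")
#' ))
#' db
#' @export
allele_db <- function(alleles, release = "synthetic") {
  stopifnot(is.data.frame(alleles))
  for (col in EXON_COLS) {
    if (is.null(alleles[[col]])) alleles[[col]] <- NA_character_
    alleles[[col]] <- toupper(as.character(alleles[[col]]))
    alleles[[col]][!is.na(alleles[[col]]) & alleles[[col]] == ""] <- NA_character_
  }
  alleles$gene <- as.character(alleles$gene)
  alleles$allele <- as.character(alleles$allele)
  dup <- alleles$allele[duplicated(alleles$allele)]
  if (length(dup)) {
    stop("duplicate allele name(s): ", paste(unique(dup), collapse = ", "))
  }
  p <- parse_allele_name(alleles$allele)
  if (!all(p$gene == alleles$gene)) {
    off <- alleles$allele[p$gene != alleles$gene]
    stop("allele name/gene mismatch for: ", paste(off, collapse = ", "))
  }
  missing23 <- is.na(alleles$exon2) | is.na(alleles$exon3)
  if (any(missing23)) {
    stop("alleles missing mandatory exon 2 or 3: ",
         paste(alleles$allele[missing23], collapse = ", "))
  }
  for (col in EXON_COLS) {
    seqs <- alleles[[col]]
    bad <- !is.na(seqs) & !grepl("^[ACGT]+$", seqs)
    if (any(bad)) {
      stop("non-ACGT sequence in ", col, " for: ",
           paste(alleles$allele[bad], collapse = ", "))
    }
  }
  alleles$first_field <- first_field(alleles$allele)
  alleles <- alleles[allele_name_order(alleles$allele), , drop = FALSE]
  rownames(alleles) <- NULL
  alleles <- alleles[, c("gene", "allele", "first_field", EXON_COLS)]
  structure(alleles,
            release = release,
            genes = sort(unique(alleles$gene)),
            class = c("allele_db", "data.frame"))
}

#' @export
print.allele_db <- function(x, ...) {
  cat(sprintf("allele_db (release %s): %d alleles [%s]\n",
              attr(x, "release"), nrow(x),
              paste(sprintf("%s: %d", attr(x, "genes"),
                            table(x$gene)[attr(x, "genes")]), collapse = ", ")))
  invisible(x)
}

#' Read an allele database
#'
#' Two simplified on-disk formats are supported:
#' \describe{
#'   \item{`"fasta"`}{one record per allele per exon, with headers of the
#'     form `>MICA*008:01 exon=2`.}
#'   \item{`"table"`}{TSV with columns `gene`, `allele`, `exon1` .. `exon6`
#'     (empty cell = exon absent), one row per allele.}
#' }
#' Full IPD-IMGT/HLA flat files are deliberately not parsed; exon-level
#' extracts in either format carry all information the assay uses.
#'
#' @param path input file.
#' @param format `"fasta"` or `"table"`.
#' @param release version label stored on the database.
#' @return An [allele_db()].
#' @export
read_allele_db <- function(path, format = c("fasta", "table"),
                           release = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "table") {
    tab <- read.delim(path, colClasses = "character", check.names = FALSE)
    need <- c("gene", "allele")
    if (!all(need %in% names(tab))) {
      stop("table format requires columns gene, allele")
    }
    return(allele_db(tab, release = release))
  }
  recs <- Biostrings::readDNAStringSet(path)
  hdr <- names(recs)
  m <- regmatches(hdr, regexec("^(\\S+)\\s+exon=([1-6])\\s*$", hdr))
  bad <- which(vapply(m, length, 1L) == 0L)
  if (length(bad)) {
    stop(sprintf("malformed fasta header at record %d: '%s'", bad[1L], hdr[bad[1L]]))
  }
  allele <- vapply(m, `[[`, "", 2L)
  exon <- as.integer(vapply(m, `[[`, "", 3L))
  key <- paste(allele, exon)
  if (anyDuplicated(key)) {
    stop("duplicate record(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  seqs <- as.character(recs)
  alleles <- unique(allele)
  tab <- data.frame(gene = parse_allele_name(alleles)$gene, allele = alleles,
                    stringsAsFactors = FALSE)
  for (k in 1:6) {
    idx <- match(paste(tab$allele, k), key)
    tab[[paste0("exon", k)]] <- ifelse(is.na(idx), NA_character_, seqs[idx])
  }
  allele_db(tab, release = release)
}

#' Write an allele database
#'
#' @param db an [allele_db()].
#' @param path output file.
#' @param format `"fasta"` or `"table"` (see [read_allele_db()]).
#' @return `path`, invisibly.
#' @export
write_allele_db <- function(db, path, format = c("fasta", "table")) {
  format <- match.arg(format)
  if (format == "table") {
    tab <- as.data.frame(db)[, c("gene", "allele", EXON_COLS)]
    for (col in EXON_COLS) tab[[col]][is.na(tab[[col]])] <- ""
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  lines <- character(0)
  for (i in seq_len(nrow(db))) {
    for (k in 1:6) {
      s <- db[[paste0("exon", k)]][i]
      if (!is.na(s)) {
        lines <- c(lines, sprintf(">%s exon=%d", db$allele[i], k), s)
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Collapse a database to protein-level allele groups
#'
#' Groups alleles by their gene-qualified first field, the protein-level
#' resolution at which cohort frequencies are reported.
#'
#' @param db an [allele_db()].
#' @return Named list: first-field name -> character vector of member
#'   allele names. Every allele appears in exactly one group.
#' @examples
#' db <- allele_db(data.frame(
#'   gene = "MICA",
#'   allele = c("MICA*008:01", "MICA*008:04", "MICA*002:01"),
#'   exon2 = "ACGT", exon3 = "TTTT"
#' ))
#' first_field_collapse(db)
#' @export
first_field_collapse <- function(db) {
  if (nrow(db) == 0L) return(setNames(list(), character(0)))
  sp <- split(db$allele, db$first_field)
  sp[sort_allele_names(names(sp))]
}

#' Genes present in an allele database
#' @param db an [allele_db()].
#' @return Character vector of gene names.
#' @export
db_genes <- function(db) attr(db, "genes")
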