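## Reading/writing GenomeStudio-final-report-like tables and STR CSVs.

.FR_COLUMNS <- c("Sample ID", "SNP Name", "Chr", "Position", "GType",
                 "B Allele Freq", "Log R Ratio")

#' Write SNP-array samples as a final-report-like table
#'
#' Tab-delimited vendor-export dialect: a \code{[Header]} block of
#' key/value lines, then a \code{[Data]} line followed by the column header
#' \code{Sample ID, SNP Name, Chr, Position, GType, B Allele Freq,
#' Log R Ratio}. Rows are sorted by sample, chromosome and position; no-call
#' genotypes are written as \code{NC}; missing numeric fields are empty.
#'
#' @param samples a \code{snp_sample} or list of them.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_final_report <- function(samples, path) {
  if (inherits(samples, "snp_sample")) samples <- list(samples)
  tab <- if (length(samples)) do.call(rbind, samples) else
    data.frame(sample_id = character(), locus_id = character(),
               chromosome = character(), position = integer(),
               gtype = character(), baf = numeric(), lrr = numeric(),
               stringsAsFactors = FALSE)
  tab <- tab[order(tab$sample_id, .chrom_order(tab$chromosome),
                   tab$position), , drop = FALSE]
  num <- function(x) ifelse(is.na(x), "", formatC(x, format = "g",
                                                  digits = 15))
  lines <- c(
    "[Header]",
    paste0("GSGT Version\tmolekaryo ", as.character(utils::packageVersion("molekaryo"))),
    paste0("Num SNPs\t", length(unique(tab$locus_id))),
    paste0("Num Samples\t", length(unique(tab$sample_id))),
    "[Data]",
    paste(.FR_COLUMNS, collapse = "\t"),
    paste(tab$sample_id, tab$locus_id, tab$chromosome, tab$position,
          ifelse(is.na(tab$gtype), "NC", tab$gtype),
          num(tab$baf), num(tab$lrr), sep = "\t")
  )
  if (nrow(tab) == 0) lines <- lines[seq_len(6)]
  .write_atomic(function(p) writeLines(lines, p), path)
}

#' Read a final-report-like table
#'
#' Inverse of [write_final_report()]. \code{NC} genotypes become missing;
#' malformed numeric fields, missing mandatory columns and duplicate
#' (sample, locus) pairs are rejected with informative errors.
#'
#' @param path file path.
#' @return Named list of \code{snp_sample} data frames, one per sample ID.
#' @export
read_final_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  data_at <- which(lines == "[Data]")
  if (length(data_at) != 1)
    stop("malformed final report: expected a single [Data] section")
  header <- strsplit(lines[data_at + 1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(.FR_COLUMNS, header)
  if (length(missing_cols))
    stop("final report lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  body <- lines[-seq_len(data_at + 1)]
  body <- body[nzchar(body)]
  if (!length(body)) return(list())
  tab <- utils::read.delim(text = body, header = FALSE, fill = TRUE,
                           col.names = make.names(header),
                           colClasses = "character")
  names(tab) <- header
  parse_num <- function(x, what, lo = -Inf, hi = Inf) {
    x[is.na(x)] <- ""
    out <- suppressWarnings(as.numeric(x))
    bad <- nzchar(trimws(x)) & is.na(out)
    if (any(bad))
      stop("malformed numeric value in column '", what, "': ",
           x[which(bad)[1]])
    out[!nzchar(trimws(x))] <- NA_real_
    if (any(!is.na(out) & (out < lo | out > hi)))
      stop("value out of range in column '", what, "'")
    out
  }
  gtype <- tab[["GType"]]
  gtype[is.na(gtype)] <- "NC"
  if (!all(gtype %in% c("AA", "AB", "BB", "NC")))
    stop("invalid GType value: ",
         setdiff(gtype, c("AA", "AB", "BB", "NC"))[1])
  gtype[gtype == "NC"] <- NA_character_
  baf <- parse_num(tab[["B Allele Freq"]], "B Allele Freq", 0, 1)
  lrr <- parse_num(tab[["Log R Ratio"]], "Log R Ratio")
  position <- parse_num(tab[["Position"]], "Position")
  key <- paste(tab[["Sample ID"]], tab[["SNP Name"]])
  if (anyDuplicated(key))
    stop("duplicate (sample, locus) pair: ", key[anyDuplicated(key)])
  out <- lapply(split(seq_len(nrow(tab)), tab[["Sample ID"]]), function(i) {
    s <- data.frame(
      sample_id = tab[["Sample ID"]][i],
      locus_id = tab[["SNP Name"]][i],
      chromosome = tab[["Chr"]][i],
      position = as.integer(position[i]),
      gtype = gtype[i],
      baf = baf[i],
      lrr = lrr[i],
      stringsAsFactors = FALSE
    )
    s <- s[order(.chrom_order(s$chromosome), s$position), ]
    rownames(s) <- NULL
    class(s) <- c("snp_sample", "data.frame")
    s
  })
  out
}

#' Write STR profiles as CSV
#'
#' Columns \code{sample_id}, \code{locus}, \code{alleles}
#' (semicolon-separated allele designations).
#'
#' @param profiles an \code{str_profile} or list of them.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_str_table <- function(profiles, path) {
  if (inherits(profiles, "str_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      sample_id = p$sample_id,
      locus = names(p$alleles),
      alleles = vapply(p$alleles, paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows))
    rows <- data.frame(sample_id = character(), locus = character(),
                       alleles = character())
  .write_atomic(function(p)
    utils::write.csv(rows, p, row.names = FALSE, quote = FALSE), path)
}

#' Read STR profiles from CSV
#'
#' Allele strings are split on \code{";"} and de-duplicated (set
#' semantics: \code{"9;9"} collapses to the single allele 9). A locus with
#' more than four distinct alleles is rejected. Loci absent from the
#' supplied panel are retained with a warning, so profiles typed on a
#' superset panel still load.
#'
#' @param path file path.
#' @param str_panel optional panel used to flag unknown loci.
#' @return Named list of \code{str_profile} objects.
#' @export
read_str_table <- function(path, str_panel = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "locus", "alleles")
  if (!all(need %in% names(tab)))
    stop("STR table lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (!is.null(str_panel)) {
    known <- c(unique(str_panel$locus), STR_SEX_MARKER)
    unknown <- setdiff(unique(tab$locus), known)
    if (length(unknown))
      warning("unknown STR locus name(s) retained: ",
              paste(unknown, collapse = ", "))
  }
  lapply(split(seq_len(nrow(tab)), tab$sample_id), function(i) {
    alleles <- lapply(tab$alleles[i], function(a)
      sort(unique(strsplit(a, ";", fixed = TRUE)[[1]])))
    names(alleles) <- tab$locus[i]
    bad <- lengths(alleles) > 4
    if (any(bad))
      stop("more than four alleles at locus ", names(alleles)[bad][1])
    .new_str_profile(tab$sample_id[i][1], alleles)
  })
}

#' Export per-locus BAF as a BED-like track
#'
#' Four tab-separated columns (chrom, start, end, BAF) for external
#' plotting; 0-based half-open intervals of width 1. Optionally restricted
#' to a selected-BAF set.
#'
#' @param sample a \code{snp_sample}.
#' @param path output file path.
#' @param selected optional \code{selected_baf} set; if given, only its
#'   loci are exported (with the mole BAF).
#' @return The path, invisibly.
#' @export
write_baf_track <- function(sample, path, selected = NULL) {
  tab <- if (is.null(selected)) {
    sample[!is.na(sample$baf),
           c("chromosome", "position", "baf")]
  } else {
    selected[!is.na(selected$baf), c("chromosome", "position", "baf")]
  }
  bed <- data.frame(chrom = tab$chromosome, start = tab$position - 1L,
                    end = tab$position, baf = tab$baf)
  .write_atomic(function(p)
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE), path)
}
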