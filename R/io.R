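#' Read chromatin loops from a BEDPE-like file
#'
#' Parses tab-separated loop calls into a canonical loop table. All
#' coordinates in the returned table are 0-based half-open (BED convention),
#' anchors are ordered so that `start1 < start2`, and only intra-chromosomal
#' (cis) loops are retained; inter-chromosomal records are dropped with a
#' warning that reports how many were skipped.
#'
#' Dialect column maps:
#' \describe{
#'   \item{`plain`}{No header. Columns 1-6 are `chrom1 start1 end1 chrom2
#'     start2 end2`; column 8, when present, is the loop q-value.}
#'   \item{`fithichip`}{Header row. Columns 1-6 are the anchor coordinates;
#'     the q-value is taken from the last column whose name contains both
#'     "q" and "val" (e.g. `Q-Value-Bias`). Missing such a column is a
#'     format error.}
#'   \item{`hiccups`}{Header row (a leading `#` is tolerated). Coordinates
#'     from `chr1,x1,x2,chr2,y1,y2`; q-value from `fdrDonut` when present,
#'     otherwise the row-wise minimum over all `fdr*` columns.}
#' }
#'
#' @param path Path to a tab-separated loop file.
#' @param dialect One of `"plain"`, `"fithichip"`, `"hiccups"`.
#' @param resolution Optional bin size in bp recorded on every loop.
#' @param sample_id Optional sample identifier recorded on every loop.
#' @return A tibble with columns `chrom1, start1, end1, chrom2, start2,
#'   end2, q_value, resolution, sample_id`.
#' @export
read_bedpe <- function(path, dialect = c("plain", "fithichip", "hiccups"),
                       resolution = NA_integer_, sample_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))

  if (dialect == "plain") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 6L)
    if (length(bad)) {
      warn(paste0("skipping ", length(bad), " malformed line(s): ",
                  paste(utils::head(bad, 5L), collapse = ", ")))
      fields <- fields[-bad]
    }
    if (!length(fields)) return(empty_loops(resolution, sample_id))
    mat <- do.call(rbind, lapply(fields, function(f) f[1:8][seq_len(8)]))
    df <- tibble(
      chrom1 = mat[, 1], start1 = as.numeric(mat[, 2]), end1 = as.numeric(mat[, 3]),
      chrom2 = mat[, 4], start2 = as.numeric(mat[, 5]), end2 = as.numeric(mat[, 6]),
      q_value = suppressWarnings(as.numeric(mat[, 8]))
    )
  } else {
    df0 <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           comment = "", name_repair = "minimal")
    names(df0)[1] <- sub("^#\\s*", "", names(df0)[1])
    if (ncol(df0) < 6L) abort("expected >= 6 tab-separated columns")
    nm <- tolower(names(df0))
    if (dialect == "fithichip") {
      qcol <- which(grepl("q", nm) & grepl("val", nm))
      if (!length(qcol)) abort("fithichip dialect requires a q-value column")
      qv <- as.numeric(df0[[qcol[length(qcol)]]])
    } else {
      fdr <- which(startsWith(nm, "fdr"))
      if (!length(fdr)) abort("hiccups dialect requires fdr* columns")
      donut <- which(nm == "fdrdonut")
      qv <- if (length(donut)) as.numeric(df0[[donut]]) else
        do.call(pmin, c(lapply(df0[fdr], as.numeric), na.rm = TRUE))
    }
    df <- tibble(
      chrom1 = as.character(df0[[1]]), start1 = as.numeric(df0[[2]]),
      end1 = as.numeric(df0[[3]]),
      chrom2 = as.character(df0[[4]]), start2 = as.numeric(df0[[5]]),
      end2 = as.numeric(df0[[6]]), q_value = qv
    )
  }

  trans <- df$chrom1 != df$chrom2
  if (any(trans)) {
    warn(paste0("skipped ", sum(trans), " inter-chromosomal loop record(s)"))
    df <- df[!trans, , drop = FALSE]
  }
  flip <- df$start1 > df$start2
  if (any(flip)) {
    tmp <- df[flip, c("start1", "end1")]
    df[flip, c("start1", "end1")] <- df[flip, c("start2", "end2")]
    df[flip, c("start2", "end2")] <- tmp
  }
  df$resolution <- as.numeric(resolution)
  df$sample_id <- as.character(sample_id)
  validate_loops(df)
  df
}

empty_loops <- function(resolution = NA_integer_, sample_id = NA_character_) {
  tibble(chrom1 = character(), start1 = numeric(), end1 = numeric(),
         chrom2 = character(), start2 = numeric(), end2 = numeric(),
         q_value = numeric(), resolution = numeric(), sample_id = character())
}

#' Validate a loop table
#'
#' Checks the loop invariants: 0-based half-open anchors with positive
#' width, intra-chromosomal records, canonical anchor ordering
#' (`start1 < start2`), q-values in (0, 1] when present, and (optionally)
#' coordinates within chromosome bounds.
#'
#' @param loops Loop tibble as returned by [read_bedpe()].
#' @param chrom_sizes Optional chromosome size tibble from
#'   [read_chrom_sizes()].
#' @return `loops`, invisibly, if valid; otherwise an error.
#' @export
validate_loops <- function(loops, chrom_sizes = NULL) {
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2") %in%
                  names(loops)))
  if (nrow(loops) == 0) return(invisible(loops))
  if (any(loops$start1 < 0) || any(loops$end1 <= loops$start1) ||
      any(loops$end2 <= loops$start2))
    abort("invalid anchor coordinates (need 0 <= start < end)")
  if (any(loops$chrom1 != loops$chrom2))
    abort("loop table contains inter-chromosomal records")
  if (any(loops$start1 > loops$start2))
    abort("anchors not in canonical order (start1 <= start2)")
  qv <- loops$q_value
  if (!is.null(qv) && any(!is.na(qv) & (qv <= 0 | qv > 1)))
    abort("q_value outside (0, 1]")
  if (!is.null(chrom_sizes)) {
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    if (any(!loops$chrom1 %in% chrom_sizes$chrom))
      abort("loop chromosome absent from chrom_sizes")
    if (any(loops$end2 > len[loops$chrom1]))
      abort("anchor exceeds chromosome length")
  }
  invisible(loops)
}

#' Write loops as plain BEDPE
#'
#' Writes the 8-column plain dialect (`chrom1 start1 end1 chrom2 start2 end2
#' name q_value`) consumed by [read_bedpe()]; round-trips are lossless for
#' coordinates and q-values.
#'
#' @param loops Loop tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  out <- data.frame(
    loops$chrom1, format_coord(loops$start1), format_coord(loops$end1),
    loops$chrom2, format_coord(loops$start2), format_coord(loops$end2),
    ".", ifelse(is.na(loops$q_value), ".", format(loops$q_value, digits = 17,
                                                  scientific = TRUE, trim = TRUE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a narrowPeak file
#'
#' Parses the 10-column ENCODE narrowPeak format. Coordinates are 0-based
#' half-open as in the file.
#'
#' @param path Path to a narrowPeak file.
#' @return A tibble with columns `chrom, start, end, name, score, strand,
#'   signal_value, p_value, q_value, peak`.
#' @export
read_narrowpeak <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand", "signal_value",
                                            "p_value", "q_value", "peak"),
                        col_types = "cddcdcdddd", progress = FALSE)
  if (any(df$signal_value < 0, na.rm = TRUE)) abort("negative signal_value")
  df
}

#' Write a narrowPeak file
#' @param peaks Peak tibble as from [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(peaks$chrom, format_coord(peaks$start),
                    format_coord(peaks$end), peaks$name, peaks$score,
                    peaks$strand, peaks$signal_value, peaks$p_value,
                    peaks$q_value, peaks$peak)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval file
#' @param path Path to a BED file (>= 3 columns, no header).
#' @return A tibble with `chrom, start, end` plus `name, score, strand` when
#'   present.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- nm[seq_len(min(ncol(df), 6L))]
  df$chrom <- as.character(df$chrom)
  df
}

#' Read a chrom.sizes file
#' @param path Two-column TSV of chromosome name and length.
#' @return A tibble with `chrom, length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "cd", progress = FALSE)
  if (anyDuplicated(df$chrom)) abort("duplicate chromosome names")
  if (any(df$length <= 0)) abort("non-positive chromosome length")
  df
}

#' Read a SNP table
#'
#' Reads a headered TSV of variants (CAUSALdb-style). Positions are 1-based;
#' they are kept 1-based in the `pos` column and converted to width-1
#' 0-based intervals only inside overlap operations.
#'
#' @param path Path to a TSV with at least `rsid, chrom, pos`; columns
#'   `posterior_prob, study_id, disease` are carried through when present.
#' @return A tibble of SNP records.
#' @export
read_snp_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("rsid", "chrom", "pos")
  if (!all(need %in% names(df))) abort("SNP table needs columns rsid, chrom, pos")
  if (any(df$pos < 1)) abort("SNP pos must be >= 1 (1-based)")
  if ("posterior_prob" %in% names(df) &&
      any(!is.na(df$posterior_prob) &
          (df$posterior_prob < 0 | df$posterior_prob > 1)))
    abort("posterior_prob outside [0, 1]")
  df$chrom <- as.character(df$chrom)
  df
}

#' Read a gene table
#' @param path Headered TSV with `gene_id, gene_name, chrom, start, end,
#'   strand` (0-based half-open coordinates).
#' @return A tibble of gene records.
#' @export
read_gene_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) abort("gene table needs gene_id, chrom, start, end, strand")
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(df$start >= df$end)) abort("gene start must be < end")
  df$chrom <- as.character(df$chrom)
  df
}

#' Read an eQTL SNP-gene pair table
#' @param path Headered TSV with `rsid, chrom, pos, gene_id` (+ optional
#'   `study_id`); `pos` is 1-based.
#' @return A tibble of eQTL pairs.
#' @export
read_eqtl_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("rsid", "chrom", "pos", "gene_id")
  if (!all(need %in% names(df))) abort("eQTL table needs rsid, chrom, pos, gene_id")
  df$chrom <- as.character(df$chrom)
  df
}

#' Read a binned contact matrix from triplet TSV
#'
#' @param path TSV with columns `bin_i, bin_j, count` (0-based bin indices,
#'   header optional).
#' @param n_bins Number of bins; inferred from the largest index when `NULL`.
#' @return A dense symmetric matrix of counts.
#' @export
read_contacts <- function(path, n_bins = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  if (is.character(df[[1]]) && !grepl("^[0-9]", df[[1]][1]))
    df <- df[-1, , drop = FALSE]
  i <- as.integer(df[[1]]); j <- as.integer(df[[2]]); x <- as.numeric(df[[3]])
  if (is.null(n_bins)) n_bins <- max(i, j) + 1L
  m <- matrix(0, n_bins, n_bins)
  m[cbind(i + 1L, j + 1L)] <- x
  m[cbind(j + 1L, i + 1L)] <- x
  m
}

#' Write a contact matrix as upper-triangle triplet TSV
#' @param mat Symmetric contact matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(mat, path) {
  idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  out <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                    count = mat[idx])
  out <- out[order(out$bin_i, out$bin_j), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
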