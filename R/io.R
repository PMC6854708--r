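#' Read a gene-level count matrix from TSV
#'
#' Expects a header row and gene identifiers in the first column. Counts must
#' be non-negative and integer-valued; duplicate gene identifiers are an
#' error. A header-only file yields a valid matrix with zero genes.
#'
#' @param path File path.
#' @return Numeric matrix (genes x samples) with gene/sample dimnames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("count matrix needs a gene-id column: ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate gene id '%s' (line %d) in %s",
                 dup[1], which(ids == dup[1])[2] + 1L, path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) > 0) {
    storage.mode(m) <- "numeric"
    bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-integer or negative count for gene '%s', sample '%s' (line %d) in %s",
        ids[bad[1, 1]], colnames(m)[bad[1, 2]], bad[1, 1] + 1L, path))
    }
    m <- round(m)
  }
  rownames(m) <- ids
  m
}

#' Write a count (or expression) matrix as TSV
#'
#' First column `gene_id`, then one column per sample.
#'
#' @param mat Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Columns `sample_id`, `patient_id`, `tissue` with tissue one of
#' normal/primary/pvtt. Duplicate sample ids are an error.
#'
#' @param path File path.
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns sample_id, patient_id, tissue: ", path)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  bad <- setdiff(unique(df$tissue), c("normal", "primary", "pvtt"))
  if (length(bad)) stop("unknown tissue role: ", bad[1])
  df[, need]
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Patients with a complete primary/pvtt pair
#'
#' @param sheet Sample sheet data.frame.
#' @return Character vector of patient ids having exactly one primary and one
#'   pvtt sample.
#' @export
paired_patients <- function(sheet) {
  tab <- table(sheet$patient_id, factor(sheet$tissue,
                                        c("normal", "primary", "pvtt")))
  rownames(tab)[tab[, "primary"] == 1 & tab[, "pvtt"] == 1]
}

#' Read / write copy-number segmentation (SEG) files
#'
#' Standard SEG columns: Sample, Chromosome, Start, End, Num_Probes,
#' Segment_Mean, with 1-based inclusive coordinates.
#'
#' @param path File path.
#' @return data.frame of segments.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  if (!all(need %in% names(df))) {
    stop("SEG file must have columns ", paste(need, collapse = ", "), ": ", path)
  }
  if (nrow(df) && any(df$Start > df$End)) stop("SEG segment with Start > End: ", path)
  df[, need]
}

#' @rdname read_seg
#' @param segments Segment data.frame.
#' @export
write_seg <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write methylation beta matrices
#'
#' TSV with probe ids in the first column; values must lie in \[0, 1\].
#'
#' @param path File path.
#' @return Numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate probe id in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (length(m) && any(!is.finite(m) | m < 0 | m > 1)) {
    stop("beta values must lie in [0, 1]: ", path)
  }
  rownames(m) <- ids
  m
}

#' @rdname read_beta_matrix
#' @param beta Beta matrix.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write probe annotation
#'
#' Columns `probe_id`, `chrom`, `pos` (1-based), `strand`, `gene_id`.
#'
#' @param path File path.
#' @return data.frame of probes.
#' @export
read_probe_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos", "strand", "gene_id")
  if (!all(need %in% names(df))) {
    stop("probe annotation must have columns ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' @rdname read_probe_annotation
#' @param probes Probe annotation data.frame.
#' @export
write_probe_annotation <- function(probes, path) {
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene annotation as BED6
#'
#' BED uses 0-based half-open coordinates; the name field holds the gene id.
#'
#' @param path File path.
#' @return data.frame with gene_id, chrom, start, end, strand, tss.
#' @export
read_gene_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("gene BED needs 6 columns (chrom start end name score strand)")
  names(df)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  data.frame(
    gene_id = df$gene_id, chrom = df$chrom,
    start = df$start, end = df$end, strand = df$strand,
    tss = ifelse(df$strand == "+", df$start + 1L, df$end),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_gene_bed
#' @param genes Gene annotation data.frame.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                   0L, genes$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write simulator truth tables
#'
#' Columns `gene_id`, `patient_id` (empty for cohort-wide effects),
#' `effect_kind`, `effect_size`.
#'
#' @param path File path.
#' @return Truth data.frame.
#' @export
read_truth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$patient_id[df$patient_id %in% c("", "NA")] <- NA_character_
  df
}

#' @rdname read_truth
#' @param truth Truth data.frame.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
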