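#' Write / read an AIM matrix as TSV
#'
#' Layout: comment header recording the polarity convention and Z label,
#' then a header row (`chrom`, `pos`, one column per individual id) and one
#' row per locus with states 0/1/2/NA. Coordinates are 1-based.
#'
#' @param x an [aim_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_aim_tsv <- function(x, path) {
  stopifnot(inherits(x, "aim_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# polarity: 0=coastal_hom 1=het 2=inland_hom",
               paste0("# z_chrom: ", x$z_chrom)), con)
  df <- data.frame(chrom = x$loci$chrom, pos = x$loci$pos,
                   t(x$states), check.names = FALSE)
  colnames(df) <- c("chrom", "pos", x$individual_ids)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aim_tsv
#' @export
read_aim_tsv <- function(path) {
  header <- readLines(path, n = 10)
  zline <- grep("^# z_chrom:", header, value = TRUE)
  z_chrom <- if (length(zline)) sub("^# z_chrom:\\s*", "", zline[1]) else "chrZ"
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  states <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  aim_matrix(states, df[, 1:2], rownames(states), z_chrom = z_chrom)
}

#' Write / read sample metadata as TSV
#'
#' Columns: `individual_id`, `age` (0/1/2), `sex`, plus any extra columns
#' present (e.g. `ancestry_q`).
#'
#' @param meta sample metadata data frame.
#' @param path file path.
#' @export
write_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a per-window recombination map as TSV
#'
#' Columns: `chrom`, `start`, `end`, `rate` (1-based closed windows).
#'
#' @param map recombination-map data frame.
#' @param path file path.
#' @export
write_recomb_tsv <- function(map, path) {
  utils::write.table(map[, c("chrom", "start", "end", "rate")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recomb_tsv
#' @export
read_recomb_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a contact matrix as coordinate-format TSV
#'
#' Upper triangle (including the diagonal) stored as `bin_i`, `bin_j`,
#' `count` (1-based bins), mirrored on read; a comment header carries
#' `bin_bp`, `n_bins`, the chromosome label and masked bins.
#'
#' @param m a [contact_matrix()].
#' @param path file path.
#' @export
write_contact_tsv <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_bp=%d n_bins=%d chrom=%s masked=%s",
                     as.integer(m$bin_bp), nrow(m$counts), m$chrom,
                     paste(m$masked, collapse = ",")), con)
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
              arr.ind = TRUE)
  df <- data.frame(bin_i = ut[, 1], bin_j = ut[, 2],
                   count = m$counts[ut])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_tsv
#' @export
read_contact_tsv <- function(path) {
  header <- readLines(path, n = 1)
  get <- function(key) sub(paste0(".*", key, "=([^ ]*).*"), "\\1", header)
  bin_bp <- as.integer(get("bin_bp"))
  n_bins <- as.integer(get("n_bins"))
  chrom <- get("chrom")
  masked_str <- get("masked")
  masked <- if (nzchar(masked_str))
    as.integer(strsplit(masked_str, ",")[[1]]) else integer()
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  counts <- matrix(0, n_bins, n_bins)
  counts[cbind(df$bin_i, df$bin_j)] <- df$count
  counts[cbind(df$bin_j, df$bin_i)] <- df$count
  contact_matrix(counts, bin_bp, chrom, masked)
}

#' Read a gene annotation from BED or GFF3
#'
#' BED intervals (0-based half-open) are converted to the package's
#' internal 1-based closed convention; GFF3 is filtered to `gene` features
#' (all features if none are typed `gene`). Requires the `rtracklayer`
#' package.
#'
#' @param path `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return Data frame `gene`, `chrom`, `start`, `end` (1-based closed).
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED/GFF annotations requires the rtracklayer package")
  gr <- rtracklayer::import(path)  # rtracklayer converts BED to 1-based
  md <- as.data.frame(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- as.data.frame(gr)
  }
  gene <- if ("Name" %in% names(md) && !all(is.na(md$Name))) md$Name
  else if ("name" %in% names(md) && !all(is.na(md$name))) md$name
  else if ("ID" %in% names(md) && !all(is.na(md$ID))) md$ID
  else paste0("gene", seq_along(gr))
  data.frame(gene = as.character(gene), chrom = as.character(md$seqnames),
             start = md$start, end = md$end, stringsAsFactors = FALSE)
}

#' Read ancestry states from a VCF
#'
#' Maps GT fields to ancestry states given a per-locus table assigning the
#' coastal and inland allele at each AIM. Requires the `vcfR` package.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param allele_table data frame `chrom`, `pos`, `coastal_allele`,
#'   `inland_allele` (bases matching REF/ALT).
#' @param z_chrom Z chromosome label.
#' @return An [aim_matrix()] over the loci present in both inputs.
#' @export
read_aim_vcf <- function(path, allele_table, z_chrom = "chrZ") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  tab_key <- paste(allele_table$chrom, allele_table$pos)
  keep <- which(key %in% tab_key)
  if (!length(keep)) stop("no VCF records match the allele table")
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  at <- allele_table[match(key[keep], tab_key), ]
  alleles <- cbind(fix[, "REF"], fix[, "ALT"])
  n_inland <- matrix(NA_integer_, nrow(gt), ncol(gt))
  split_gt <- function(g) strsplit(g, "[/|]")
  for (i in seq_len(nrow(gt))) {
    inland <- at$inland_allele[i]
    parts <- split_gt(gt[i, ])
    n_inland[i, ] <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".")) return(NA_integer_)
      base <- alleles[i, as.integer(p) + 1L]
      sum(base == inland)
    }, integer(1))
  }
  aim_matrix(t(n_inland),
             data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"])),
             colnames(gt), z_chrom = z_chrom)
}

#' Write a scan result as TSV
#'
#' @param scan a `scan_result` data frame.
#' @param path file path.
#' @export
write_scan_tsv <- function(scan, path) {
  df <- scan
  df$members <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
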