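#' Read genotypes from a VCF file
#'
#' Keeps biallelic SNV records only (multi-allelic sites and indels are
#' skipped, with the skip count reported). Genotypes are recoded for inbred
#' strains: `0/0 -> 0`, `1/1 -> 1`, heterozygous or missing -> `NA`.
#'
#' @param path Path to a VCF (optionally gzip-compressed) with a GT field.
#' @return A [geno_matrix()] (strains = VCF samples). The number of skipped
#'   records is attached as `attr(, "n_skipped")`.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) abort("cannot parse VCF: ", conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  keep <- fix$REF %in% bases & fix$ALT %in% bases
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(paste0("read_vcf: skipped ", n_skipped, " non-biallelic-SNV record(s)."))
  }
  if (!any(keep)) abort("no biallelic SNV records in ", path)
  gt <- vcfR::extract.gt(v[keep, ], element = "GT")
  samples <- colnames(gt)
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0")] <- 0
    out[g %in% c("1/1", "1")] <- 1
    out
  }
  fixk <- fix[keep, , drop = FALSE]
  ids <- fixk$ID
  ids[is.na(ids) | ids == "."] <- paste0(fixk$CHROM, "_", fixk$POS)[is.na(ids) | ids == "."]
  map <- tibble::tibble(marker = ids, chrom = fixk$CHROM, bp = as.integer(fixk$POS))
  dosage <- t(matrix(code(as.vector(gt)), nrow = nrow(map)))  # strains x markers
  dimnames(dosage) <- list(samples, map$marker)
  G <- geno_matrix(dosage, map)
  attr(G, "n_skipped") <- n_skipped
  G
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotypes; `NA` dosages become `./.`.
#'
#' @param G A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  map <- G$map
  d <- G$dosage
  gt <- matrix("./.", ncol(d), nrow(d))
  gt[t(d) == 0] <- "0/0"
  gt[t(d) == 1] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  body <- paste(map$chrom, map$bp, map$marker, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' @param path TSV with a `transcript` column followed by one column per
#'   sample.
#' @param meta TSV path or data frame with columns `sample`, `strain`,
#'   `replicate` covering every sample column.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, meta) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "transcript") abort("expression TSV must start with a 'transcript' column.")
  if (is.character(meta) && length(meta) == 1) {
    meta <- readr::read_tsv(meta, show_col_types = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  values <- as.matrix(tab[, -1])
  rownames(values) <- tab$transcript
  absent <- setdiff(colnames(values), meta$sample)
  if (length(absent) > 0) {
    abort("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  }
  if (any(values < 0, na.rm = TRUE)) abort("negative expression value in ", path)
  expr_matrix(values, meta)
}

#' Write an expression matrix (values only) as TSV
#' @param expr An [expr_matrix()]; masked cells are written as NA.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  v <- expr_values(expr)
  tab <- tibble::as_tibble(v, rownames = "transcript")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a transcript annotation TSV
#'
#' Expected columns: `transcript`, `gene`, `chrom`, `tss_bp` (1-based),
#' `strand` (+/-).
#' @param path TSV path.
#' @return A validated tibble.
#' @export
read_annotation <- function(path) {
  validate_annotation(readr::read_tsv(path, show_col_types = FALSE))
}

#' Read a genetic map TSV
#'
#' Expected columns: `marker`, `chrom`, `bp`, `cM`; cM must be monotone
#' non-decreasing within each chromosome.
#' @param path TSV path.
#' @return A tibble.
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("marker", "chrom", "bp", "cM")
  if (!all(need %in% names(map))) abort("genetic map needs columns: ", paste(need, collapse = ", "))
  if (any(map$cM < 0)) abort("cM must be non-negative.")
  mono <- all(tapply(map$cM, map$chrom, function(x) !is.unsorted(x)))
  if (!mono) abort("cM must be monotone non-decreasing within chromosome.")
  map
}

#' Read per-strain divergent-region masks from BED
#'
#' BED convention: 0-based half-open intervals; the 4th column names the
#' strain.
#' @param path BED path.
#' @return Tibble (strain, chrom, start, end), normalized (sorted,
#'   non-overlapping per strain).
#' @export
read_bed_masks <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "strain"),
                         show_col_types = FALSE)
  validate_masks(bed)
}

#' Write divergent-region masks as BED
#' @param masks Tibble (strain, chrom, start, end).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_masks <- function(masks, path) {
  readr::write_tsv(masks[, c("chrom", "start", "end", "strain")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV (strain, value)
#' @param path TSV path.
#' @return A tibble.
#' @export
read_phenotype <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("strain", "value") %in% names(ph))) abort("phenotype needs columns strain, value.")
  ph
}

#' Write any record table as deterministic TSV
#'
#' Tab-separated, UTF-8, '\n' line endings, stable column order.
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path TSV path.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write all pieces of a simulated study to a directory
#'
#' Emits `genotypes.vcf`, `expression_counts.tsv`, `expression_tpm.tsv`,
#' `samples.tsv`, `annotation.tsv`, `genetic_map.tsv`,
#' `divergent_masks.bed`, `phenotype.tsv` and `truth.tsv`.
#'
#' @param study A [sim_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(study$genotypes, file.path(dir, "genotypes.vcf"))
  write_expression(study$counts, file.path(dir, "expression_counts.tsv"))
  write_expression(study$tpm, file.path(dir, "expression_tpm.tsv"))
  write_table(study$counts$samples, file.path(dir, "samples.tsv"))
  write_table(study$annotation, file.path(dir, "annotation.tsv"))
  write_table(study$genotypes$map, file.path(dir, "genetic_map.tsv"))
  write_bed_masks(study$masks, file.path(dir, "divergent_masks.bed"))
  write_table(study$phenotype, file.path(dir, "phenotype.tsv"))
  write_table(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
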