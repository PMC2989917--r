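#' Read a gene annotation from BED or GFF3
#'
#' Uses `rtracklayer::import()`, so BED's 0-based half-open coordinates are
#' converted to the 1-based inclusive convention used internally.  Gene ids
#' come from the `name` (BED) / `ID` or `Name` (GFF3) attribute, falling
#' back to `gene<i>`.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `NULL`, `"bed"` or `"gff3"`.
#' @return annotation `data.frame`: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_annotation <- function(path, format = NULL) {
  gr <- if (is.null(format)) rtracklayer::import(path)
        else rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  id <- if ("name" %in% names(md)) md$name
        else if ("ID" %in% names(md)) md$ID
        else if ("Name" %in% names(md)) md$Name
        else paste0("gene", seq_along(gr))
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation to BED or GFF3
#'
#' @param annotation annotation `data.frame`.
#' @param path output path.
#' @param format `"bed"` (0-based half-open on disk) or `"gff3"` (1-based
#'   inclusive).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  strand <- annotation$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end),
    strand = strand)
  if (format == "bed") {
    S4Vectors::mcols(gr)$name <- annotation$gene_id
    rtracklayer::export(gr, path, format = "bed")
  } else {
    S4Vectors::mcols(gr)$ID <- annotation$gene_id
    S4Vectors::mcols(gr)$type <- "gene"
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Write a genotype study to a directory of TSV files
#'
#' Emits `genotypes.tsv` (subjects x SNPs dose matrix, `NA` for missing),
#' `snp_map.tsv` (`snp_id`, `chrom`, `pos` 1-based) and, if phenotypes are
#' present, `phenotypes.tsv` (`subject_id`, `status`, `age`, `subtype`).
#'
#' @param study a `genotype_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "genotype_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- data.table::data.table(subject_id = study$subject_id)
  geno <- cbind(geno, data.table::as.data.table(study$dose))
  data.table::fwrite(geno, file.path(dir, "genotypes.tsv"), sep = "\t")
  data.table::fwrite(study$map[, c("snp_id", "chrom", "pos")],
                     file.path(dir, "snp_map.tsv"), sep = "\t")
  if (!is.null(study$status)) {
    ph <- data.frame(subject_id = study$subject_id, status = study$status,
                     age = study$age,
                     subtype = if (is.null(study$subtype)) NA_character_
                               else study$subtype)
    data.table::fwrite(ph, file.path(dir, "phenotypes.tsv"), sep = "\t")
  }
  invisible(dir)
}

#' Read a genotype study from a directory of TSV files
#'
#' Inverse of [write_study()]; `phenotypes.tsv` is optional.
#'
#' @param dir directory containing the TSV files.
#' @return a `genotype_study`.
#' @export
read_study <- function(dir) {
  geno <- data.table::fread(file.path(dir, "genotypes.tsv"), sep = "\t",
                            data.table = FALSE)
  map <- data.table::fread(file.path(dir, "snp_map.tsv"), sep = "\t",
                           data.table = FALSE)
  subject_id <- as.character(geno$subject_id)
  dose <- as.matrix(geno[, -1, drop = FALSE])
  study <- structure(list(map = map, dose = dose, subject_id = subject_id,
                          status = NULL, age = NULL, subtype = NULL,
                          truth = NULL), class = "genotype_study")
  ph_path <- file.path(dir, "phenotypes.tsv")
  if (file.exists(ph_path)) {
    ph <- data.table::fread(ph_path, sep = "\t", data.table = FALSE)
    ix <- match(subject_id, as.character(ph$subject_id))
    study$status <- ph$status[ix]
    study$age <- ph$age[ix]
    study$subtype <- as.character(ph$subtype[ix])
  }
  study
}

#' Write a ranked gene list to TSV
#'
#' @param ranked_list a `ranked_gene_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked_list, path) {
  data.table::fwrite(as.data.frame(ranked_list), path, sep = "\t")
  invisible(path)
}

#' Read a ranked gene list from TSV
#'
#' @param path file written by [write_ranked_list()].
#' @return a `ranked_gene_list`.
#' @export
read_ranked_list <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  class(d) <- c("ranked_gene_list", "data.frame")
  d
}

#' Read genotype count tables from TSV or JSON
#'
#' TSV layout: columns `snp`, `group` (`"controls"`/`"cases"`), `n_AA`,
#' `n_Aa`, `n_aa`, two rows per SNP.  JSON layout: an array of objects with
#' the same fields.
#'
#' @param path file path (`.json` parsed as JSON, anything else as TSV).
#' @return named list of [count_table()]s.
#' @export
read_count_tables <- function(path) {
  d <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else
    data.table::fread(path, sep = "\t", data.table = FALSE)
  needed <- c("snp", "group", "n_AA", "n_Aa", "n_aa")
  if (!all(needed %in% names(d)))
    .stopf("count table file needs columns: %s", paste(needed, collapse = ", "))
  out <- lapply(split(d, d$snp), function(s) {
    ctrl <- s[s$group == "controls", c("n_AA", "n_Aa", "n_aa")]
    case <- s[s$group == "cases", c("n_AA", "n_Aa", "n_aa")]
    if (nrow(ctrl) != 1 || nrow(case) != 1)
      .stopf("SNP %s needs exactly one controls and one cases row", s$snp[1])
    count_table(s$snp[1], as.numeric(ctrl), as.numeric(case))
  })
  out
}
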