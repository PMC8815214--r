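#' Write a genotype panel to VCF
#'
#' Emits a minimal VCFv4.2 file: one bi-allelic record per SNP (`REF=A`,
#' `ALT=G`, the ALT allele being the panel's '1' allele), GT-only FORMAT.
#' Dosage 1 heterozygotes are written as `0/1` (`0|1` when `phased = TRUE`,
#' the convention for coalescent haplotype panels; phase is arbitrary since
#' panels store dosages). Positions come from `panel$positions` (rounded up
#' to >= 1) or default to 1, 2, ... Subpopulation labels are written
#' alongside as a two-column TSV (`sample_id`, `subpop`) when
#' `subpop_path` is given.
#'
#' VCF `POS` is 1-based; internal positions are kept as-is (simulated
#' panels already use base coordinates).
#'
#' @param panel A [genotype_panel()].
#' @param path Output `.vcf` path.
#' @param phased Write phased genotype separators (default `FALSE`).
#' @param subpop_path Optional path for the subpopulation TSV.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, phased = FALSE, subpop_path = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  n <- nrow(dos); s <- ncol(dos)
  ids <- rownames(dos)
  pos <- if (!is.null(panel$positions)) pmax(1L, ceiling(panel$positions)) else seq_len(s)
  sep <- if (phased) "|" else "/"
  gt_code <- c(paste0("0", sep, "0"), paste0("0", sep, "1"),
               paste0("1", sep, "1"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=epstrat",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(s), function(v) {
    g <- dos[, v]
    gt <- ifelse(is.na(g), paste0(".", sep, "."), gt_code[g + 1L])
    paste(c("1", pos[v], colnames(dos)[v], "A", "G", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(subpop_path)) {
    readr::write_tsv(tibble::tibble(sample_id = ids, subpop = panel$subpop),
                     subpop_path)
  }
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Parses GT fields of bi-allelic diploid records into ALT-allele dosages.
#' Missing genotypes (`./.`) become `NA` and are excluded from the
#' per-subpopulation frequency estimates. Multi-allelic records are
#' rejected unless `drop_multiallelic = TRUE`, in which case they are
#' skipped.
#'
#' @param path VCF path.
#' @param subpop Either an integer label vector (one per sample), the path
#'   of a two-column `sample_id`/`subpop` TSV, or `NULL` (all samples get
#'   subpopulation 1).
#' @param drop_multiallelic Skip multi-ALT records instead of erroring.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, subpop = NULL, drop_multiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", v@fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (!drop_multiallelic) {
      stop("multi-allelic records present; set drop_multiallelic = TRUE ",
           "to skip them")
    }
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[|/]", "", gt)
  if (any(nchar(stats::na.omit(as.vector(alleles))) != 2L)) {
    stop("non-diploid GT encountered")
  }
  a1 <- substr(alleles, 1, 1)
  a2 <- substr(alleles, 2, 2)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  dos <- matrix(as.integer(a1) + as.integer(a2),
                nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE)
  rownames(dos) <- colnames(gt)
  colnames(dos) <- v@fix[, "ID"]
  ids <- colnames(gt)
  sp <- if (is.null(subpop)) {
    rep(1L, length(ids))
  } else if (is.character(subpop) && length(subpop) == 1L) {
    tab <- readr::read_tsv(subpop, show_col_types = FALSE)
    as.integer(tab$subpop[match(ids, tab$sample_id)])
  } else {
    as.integer(subpop)
  }
  freq_by <- function(d) unname(colMeans(d, na.rm = TRUE) / 2)
  f1 <- if (any(sp == 1L)) freq_by(dos[sp == 1L, , drop = FALSE]) else rep(NA_real_, ncol(dos))
  f2 <- if (any(sp == 2L)) freq_by(dos[sp == 2L, , drop = FALSE]) else rep(NA_real_, ncol(dos))
  genotype_panel(
    dos, sp,
    snp_freqs = tibble::tibble(snp_id = colnames(dos), freq1 = f1, freq2 = f2),
    positions = as.numeric(v@fix[, "POS"])
  )
}

#' Dosage-table persistence
#'
#' Fast-reload tabular format: a TSV with `sample_id`, `subpop`, then one
#' integer column per SNP.
#'
#' @param panel A [genotype_panel()].
#' @param path TSV path.
#' @return `write_dosage_tsv`: `path` invisibly; `read_dosage_tsv`: a
#'   [genotype_panel()].
#' @export
write_dosage_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  tab <- tibble::as_tibble(panel$dosages)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(panel$dosages),
                   subpop = panel$subpop),
    tab
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  dos <- as.matrix(tab[, -(1:2)])
  rownames(dos) <- tab$sample_id
  genotype_panel(dos, tab$subpop)
}

#' GRM persistence
#'
#' Square plain-text format: a TSV whose header row and first column hold
#' sample ids. GCTA-compatible format: `prefix.grm.id` (FID/IID) plus the
#' gzipped triplet text `prefix.grm.gz` with columns index1, index2,
#' number of SNPs, and relatedness (lower triangle including the
#' diagonal).
#'
#' @param model A `relatedness_model`.
#' @param path,prefix Output locations.
#' @param tol Asymmetry tolerance on read.
#' @return Writers return their target invisibly; readers return a
#'   `relatedness_model`.
#' @export
write_grm_tsv <- function(model, path) {
  stopifnot(inherits(model, "relatedness_model"))
  tab <- tibble::as_tibble(model$grm, .name_repair = ~ model$ids)
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = model$ids), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path, tol = 1e-8) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- tab$sample_id
  G <- as.matrix(tab[, -1])
  if (!identical(colnames(G), ids)) stop("GRM id mismatch between header and rows")
  dimnames(G) <- list(ids, ids)
  if (max(abs(G - t(G))) > tol) stop("GRM asymmetric beyond tolerance")
  as_relatedness_model((G + t(G)) / 2, ids = ids)
}

#' @rdname write_grm_tsv
#' @export
write_grm_gcta <- function(model, prefix) {
  stopifnot(inherits(model, "relatedness_model"))
  n <- nrow(model$grm)
  idx <- which(lower.tri(model$grm, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  writeLines(sprintf("%d\t%d\t%d\t%.10g", idx[, 1], idx[, 2],
                     ifelse(is.na(model$n_snps_used), 0L, model$n_snps_used),
                     model$grm[idx]), con)
  close(con)
  readr::write_tsv(tibble::tibble(fid = model$ids, iid = model$ids),
                   paste0(prefix, ".grm.id"), col_names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_tsv
#' @export
read_grm_gcta <- function(prefix) {
  ids <- readr::read_tsv(paste0(prefix, ".grm.id"), col_names = c("fid", "iid"),
                         show_col_types = FALSE)$iid
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")),
                           col.names = c("i", "j", "n_snps", "value"))
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(tri$i, tri$j)] <- tri$value
  G[cbind(tri$j, tri$i)] <- tri$value
  as_relatedness_model(G, ids = ids, n_snps_used = tri$n_snps[1])
}

#' Phenotype-table persistence
#'
#' TSV with `sample_id`, `y_quantitative` and `y_binary` (`NA` for
#' individuals outside the extreme sample), the PLINK-style phenotype
#' layout with a single id column.
#'
#' @param sample_id Cohort sample ids.
#' @param y Quantitative phenotype vector.
#' @param eps An `eps_sample` from [eps_select()] (or `NULL` to omit the
#'   binary column).
#' @param path TSV path.
#' @return Writer: `path` invisibly; reader: a tibble.
#' @export
write_phenotype_tsv <- function(sample_id, y, eps, path) {
  y_binary <- rep(NA_integer_, length(y))
  if (!is.null(eps)) y_binary[eps$index] <- eps$group
  readr::write_tsv(
    tibble::tibble(sample_id = sample_id, y_quantitative = y,
                   y_binary = y_binary),
    path
  )
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Association-results persistence
#'
#' One row per tested variant or set; plain TSV.
#'
#' @param results Tibble of association output.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
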