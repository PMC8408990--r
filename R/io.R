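# Tab-delimited formats with declared headers. All files round-trip
# bit-exactly for integers/strings and beyond 12 significant digits for
# reals (readr writes shortest round-trip representations). Positions are
# 1-based closed intervals everywhere except the region blacklist
# (half-open), as stated in the format docs.

.twas_schemas <- list(
  sumstats = list(cols = c(SNP = "c", A1 = "c", A2 = "c", Z = "d", N = "d")),
  weights = list(cols = c(gene = "c", tissue = "c", snp_id = "c",
                          chrom = "c", pos = "d", effect_allele = "c",
                          other_allele = "c", weight = "d")),
  extra = list(cols = c(gene = "c", tissue = "c", n_snps = "d", r = "d",
                        p = "d", n_eval = "d", r2 = "d", lambda1 = "d",
                        lambda2 = "d")),
  covariance = list(cols = c(gene = "c", snp_i = "c", snp_j = "c",
                             value = "d")),
  associations = list(cols = c(gene = "c", tissue = "c", z_gene = "d",
                               p = "d", effect = "d", ci_low = "d",
                               ci_high = "d", or = "d", or_low = "d",
                               or_high = "d", sigma_g = "d",
                               n_snps_used = "d")),
  combined = list(cols = c(gene = "c", n_tissues = "d", tissue_ps = "c",
                           t_stat = "d", p_combined = "d",
                           significant = "l", excluded_region = "l")),
  finemap = list(cols = c(region = "d", gene = "c", twas_z = "d",
                          pip = "d", in_credible_set = "l",
                          null_model_posterior = "d")),
  snp_meta = list(cols = c(snp_id = "c", chrom = "c", pos = "d",
                           effect_allele = "c", other_allele = "c",
                           af = "d", block = "d")),
  gene_meta = list(cols = c(gene_id = "c", chrom = "c", tss = "d",
                            tes = "d", block = "d"))
)

#' Read a pipeline file
#'
#' Tab-delimited readers for the pipeline's own formats, with strict
#' header checking and per-cell validation; a malformed row is rejected
#' with its 1-based file line number (the header is line 1).
#'
#' @param path File path.
#' @param kind One of `"sumstats"`, `"weights"`, `"extra"`,
#'   `"covariance"`, `"associations"`, `"combined"`, `"finemap"`,
#'   `"snp_meta"`, `"gene_meta"`, `"expression"`, `"panel"` (dosage
#'   table), `"truth"` (JSON).
#' @return A tibble (or list for `"truth"`).
#' @export
read_twas_file <- function(path, kind) {
  if (kind == "truth") return(read_truth_json(path))
  if (kind %in% c("expression", "panel")) return(read_sample_matrix(path, kind))
  schema <- .twas_schemas[[kind]]
  if (is.null(schema))
    abort(sprintf("unknown format kind '%s'", kind),
          class = "crosstwas_format_error")
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  want <- names(schema$cols)
  missing <- setdiff(want, names(raw))
  if (length(missing))
    abort(sprintf("%s: header mismatch; missing columns: %s",
                  basename(path), paste(missing, collapse = ", ")),
          class = "crosstwas_format_error")
  raw <- raw[want]
  for (j in seq_along(want)) {
    type <- schema$cols[[j]]
    if (type == "d") {
      v <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(v) & !(is.na(raw[[j]]) | raw[[j]] == "NA"))
      if (length(bad))
        abort(sprintf("%s: non-numeric value in column '%s' at line %d",
                      basename(path), want[j], bad[1] + 1L),
              class = "crosstwas_format_error")
      raw[[j]] <- v
    } else if (type == "l") {
      v <- raw[[j]] %in% "TRUE"
      bad <- which(!raw[[j]] %in% c("TRUE", "FALSE", "NA", NA))
      if (length(bad))
        abort(sprintf("%s: non-logical value in column '%s' at line %d",
                      basename(path), want[j], bad[1] + 1L),
              class = "crosstwas_format_error")
      v[raw[[j]] %in% c("NA", NA)] <- NA
      raw[[j]] <- v
    }
  }
  raw
}

#' Write a pipeline file
#'
#' @param x Object to write (tibble, matrix for `"expression"`/`"panel"`,
#'   list for `"truth"`).
#' @inheritParams read_twas_file
#' @return `path`, invisibly.
#' @export
write_twas_file <- function(x, path, kind) {
  if (kind == "truth") return(write_truth_json(x, path))
  if (kind %in% c("expression", "panel")) return(write_sample_matrix(x, path))
  schema <- .twas_schemas[[kind]]
  if (is.null(schema))
    abort(sprintf("unknown format kind '%s'", kind),
          class = "crosstwas_format_error")
  want <- names(schema$cols)
  for (w in setdiff(want, names(x))) x[[w]] <- NA
  x <- as_tibble(x)[want]
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

read_sample_matrix <- function(path, kind) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (names(raw)[1] != "sample_id")
    abort(sprintf("%s: header mismatch; missing columns: sample_id",
                  basename(path)), class = "crosstwas_format_error")
  m <- as.matrix(raw[-1])
  rownames(m) <- raw$sample_id
  m
}

write_sample_matrix <- function(x, path) {
  tbl <- as_tibble(x, rownames = "sample_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$true_weights <- lapply(x$true_weights, function(m) {
    mm <- as.matrix(m)
    storage.mode(mm) <- "double"
    mm
  })
  x$gene_trait_effects <- unlist(x$gene_trait_effects)
  x$marginal_snp_effects <- unlist(x$marginal_snp_effects)
  x
}

write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = FALSE,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(path)
}

#' Convert per-gene covariance matrices to/from the long TSV layout
#'
#' The on-disk layout stores the upper triangle (including the diagonal)
#' as rows `gene, snp_i, snp_j, value`.
#'
#' @param ld An `ld_covariance` (named list of matrices).
#' @return `cov_to_long()`: a tibble; `long_to_cov()`: an
#'   `ld_covariance`.
#' @export
cov_to_long <- function(ld) {
  purrr::map_dfr(names(ld), function(g) {
    m <- ld[[g]]
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    tibble(gene = g, snp_i = rownames(m)[idx[, 1]],
           snp_j = colnames(m)[idx[, 2]], value = m[idx])
  })
}

#' @rdname cov_to_long
#' @param tbl Long-format covariance tibble.
#' @export
long_to_cov <- function(tbl) {
  out <- lapply(split(tbl, tbl$gene), function(x) {
    ids <- unique(c(x$snp_i, x$snp_j))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(x$snp_i, x$snp_j)] <- x$value
    m[cbind(x$snp_j, x$snp_i)] <- x$value
    m
  })
  structure(out[unique(tbl$gene)], class = "ld_covariance")
}

#' Read/write GWAS summary statistics
#'
#' Tab-delimited with header `SNP, A1, A2, Z, N` (`A1` is the effect
#' allele).
#'
#' @param path File path.
#' @return A `gwas_summary` tibble.
#' @export
read_gwas_sumstats <- function(path) {
  raw <- read_twas_file(path, "sumstats")
  out <- tibble(snp_id = raw$SNP, effect_allele = raw$A1,
                other_allele = raw$A2, z = raw$Z, n = raw$N)
  class(out) <- c("gwas_summary", class(out))
  out
}

#' @rdname read_gwas_sumstats
#' @param gwas A `gwas_summary` tibble.
#' @export
write_gwas_sumstats <- function(gwas, path) {
  write_twas_file(tibble(SNP = gwas$snp_id, A1 = gwas$effect_allele,
                         A2 = gwas$other_allele, Z = gwas$z, N = gwas$n),
                  path, "sumstats")
}

#' Read/write a weight database
#'
#' Two TSVs: `weights.tsv` (per-SNP weights) and `extra.tsv` (per-model
#' performance); the loader round-trips exactly.
#'
#' @param db A `weight_db`.
#' @param dir Directory.
#' @return `read_weight_db()`: a `weight_db`.
#' @export
write_weight_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_twas_file(db$weights, file.path(dir, "weights.tsv"), "weights")
  write_twas_file(db$extra, file.path(dir, "extra.tsv"), "extra")
  invisible(dir)
}

#' @rdname write_weight_db
#' @export
read_weight_db <- function(dir) {
  structure(list(
    weights = read_twas_file(file.path(dir, "weights.tsv"), "weights"),
    extra = read_twas_file(file.path(dir, "extra.tsv"), "extra")),
    class = "weight_db")
}
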