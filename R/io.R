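#' Write a genome-scan summary-statistics table
#'
#' Tab-delimited text with `# key: value` header comments recording run
#' metadata (correction method, fitted parameters, lambda), then the scan
#' columns.
#'
#' @param scan A `gc_scan` data.frame (or compatible).
#' @param file Output path.
#' @param meta Named list of metadata written as header comments.
#' @return `file`, invisibly.
#' @export
write_scan <- function(scan, file, meta = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
               con)
  utils::write.table(scan, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a genome-scan summary-statistics table
#'
#' @param file Path written by [write_scan()] (or any tab-delimited table
#'   with a header row; `#` lines are treated as metadata).
#' @return A `gc_scan` data.frame; header metadata in `attr(, "meta")`.
#' @export
read_scan <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*:\\s*", "", kv)
    meta[[k]] <- v
  }
  scan <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
  class(scan) <- c("gc_scan", "data.frame")
  attr(scan, "meta") <- meta
  scan
}

#' Write a genotype matrix as delimited text
#'
#' Rows are SNPs, columns are individuals (the conventional transposed
#' layout of genotype text files); first column holds the SNP identifier.
#'
#' @param G Genotype matrix, individuals x SNPs (hard calls or dosages).
#' @param file Output path.
#' @param snp_ids Optional identifiers (default `snp1..snpM`).
#' @return `file`, invisibly.
#' @export
write_genotypes <- function(G, file, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(G)))
  out <- data.frame(snp = snp_ids, t(G), check.names = FALSE)
  colnames(out) <- c("snp", paste0("id", seq_len(nrow(G))))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a genotype matrix written by [write_genotypes()]
#'
#' @param file Path to the SNPs-by-individuals table.
#' @return A numeric matrix, individuals x SNPs, with SNP ids as column
#'   names.
#' @export
read_genotypes <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d[[1]]
  G <- t(as.matrix(d[, -1, drop = FALSE]))
  dimnames(G) <- list(rownames(G), ids)
  G
}

#' Write / read a phenotype vector
#'
#' @param y Phenotype vector (binary 0/1 or quantitative).
#' @param file Path.
#' @return `file` (write) or a numeric vector (read).
#' @export
write_phenotype <- function(y, file) {
  utils::write.table(data.frame(phenotype = y), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")$phenotype
}

#' Read a flat key-value simulation config file
#'
#' Lines of the form `key: value` (or `key = value`); numeric values and
#' comma-separated numeric vectors are coerced; keys must match
#' [sim_config()] arguments.
#'
#' @param file Path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(file) {
  lines <- grep("^\\s*(#|$)", readLines(file), value = TRUE, invert = TRUE)
  args <- list()
  for (l in lines) {
    kv <- strsplit(l, "[:=]", fixed = FALSE)[[1]]
    if (length(kv) < 2) next
    k <- trimws(kv[1])
    v <- trimws(paste(kv[-1], collapse = ":"))
    vs <- strsplit(v, ",")[[1]]
    num <- suppressWarnings(as.numeric(trimws(vs)))
    args[[k]] <- if (!anyNA(num)) num else v
  }
  do.call(sim_config, args)
}
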