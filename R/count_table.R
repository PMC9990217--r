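#' Construct a validated ASV count table
#'
#' An ASV count table is a plain numeric matrix with ASVs in rows and samples
#' in columns, integral non-negative entries, and unique row and column names.
#' All pipeline entry points validate their input with the same rules, so a
#' matrix built elsewhere (e.g. simulated, or extracted from a
#' `phyloseq`/`biomformat` object) can be passed directly.
#'
#' @param counts numeric matrix (or coercible) of non-negative integral counts.
#' @param asv_ids,sample_ids optional character vectors of unique identifiers;
#'   default to the dimnames of `counts`.
#' @return the validated count matrix with dimnames set.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 3,
#'             dimnames = list(paste0("asv", 1:3), c("s1", "s2")))
#' ct <- count_table(m)
count_table <- function(counts, asv_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(asv_ids) || is.null(sample_ids)) {
    stop("count table needs ASV identifiers (rownames) and sample identifiers (colnames)")
  }
  if (length(asv_ids) != nrow(counts)) {
    stop("length of `asv_ids` (", length(asv_ids), ") does not match row count (",
         nrow(counts), ")")
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length of `sample_ids` (", length(sample_ids),
         ") does not match column count (", ncol(counts), ")")
  }
  rownames(counts) <- as.character(asv_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_count_table(counts)
}

#' Validate an ASV count table
#'
#' Checks the count-table invariants: numeric, no missing values, all entries
#' integral and non-negative, unique ASV and sample identifiers. Errors name
#' the first offending cell or the duplicated identifier.
#'
#' @param x matrix as in [count_table()].
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("count table must be a numeric matrix (ASVs in rows, samples in columns)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count table must carry ASV rownames and sample colnames")
  }
  dup_r <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_r)) stop("duplicate ASV id(s): ", paste(unique(dup_r), collapse = ", "))
  dup_c <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_c)) stop("duplicate sample id(s): ", paste(unique(dup_c), collapse = ", "))
  if (anyNA(x)) {
    idx <- arrayInd(which(is.na(x))[1L], dim(x))
    stop("missing count at ASV '", rownames(x)[idx[1L]], "', sample '",
         colnames(x)[idx[2L]], "'")
  }
  bad <- x < 0 | abs(x - round(x)) > 1e-8
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1L], dim(x))
    stop("negative or non-integer count (", x[idx], ") at ASV '",
         rownames(x)[idx[1L]], "', sample '", colnames(x)[idx[2L]], "'")
  }
  x
}

#' Read an ASV count table from TSV or BIOM
#'
#' The TSV dialect is the common export format: first column ASV id, header
#' row of sample ids, tab-separated integer cells. BIOM files (1.0 JSON or
#' 2.x HDF5) are read through the `biomformat` package when installed.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose logical; set `TRUE` for tables written samples-in-rows.
#' @return a validated count matrix (see [count_table()]).
#' @export
read_count_table <- function(path, format = c("tsv", "biom"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("count table TSV needs an id column plus at least one sample column")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- ids
  }
  if (transpose) m <- t(m)
  if (!is.numeric(m)) stop("count table contains non-numeric cells")
  count_table(m)
}

#' Write an ASV count table as TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x, p))`
#' returns a matrix identical to `x`.
#'
#' @param x count matrix.
#' @param path output file path.
#' @param id_column header for the ASV id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, id_column = "asv_id") {
  x <- validate_count_table(x)
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Requires columns `sample_id`, `site`, `land_use_class`, `date` (ISO-8601);
#' a `year` column is derived from `date` when absent. Any additional numeric
#' columns are kept as environmental covariates.
#'
#' @param path TSV file path.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta data.frame to validate in place of a file.
#' @export
validate_sample_metadata <- function(meta) {
  req <- c("sample_id", "site", "land_use_class", "date")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop("duplicate sample_id(s) in metadata: ", paste(unique(dup), collapse = ", "))
  d <- as.Date(as.character(meta$date), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable date(s) (expect ISO-8601 YYYY-MM-DD): ",
         paste(utils::head(meta$date[is.na(d)], 3L), collapse = ", "))
  }
  meta$date <- d
  if (is.null(meta$year)) meta$year <- as.integer(format(d, "%Y"))
  meta
}

#' Merge two filter-fraction count tables
#'
#' Water samples filtered through two pore sizes yield two sequencing
#' libraries per sample; their ASV counts are summed per (ASV, sample) into a
#' single table before rarefaction. The ASV sets are unioned, with absent
#' ASVs counted as zero. The operation is commutative and associative.
#'
#' @param a,b count matrices whose sample ids refer to the same water samples.
#' @param strict logical; if `TRUE` (default) a sample present in only one
#'   input is an error, otherwise it is kept with the missing fraction treated
#'   as all-zero (with a warning).
#' @return merged count matrix over the union of ASVs and samples.
#' @export
merge_fraction_tables <- function(a, b, strict = TRUE) {
  a <- validate_count_table(a)
  b <- validate_count_table(b)
  only_a <- setdiff(colnames(a), colnames(b))
  only_b <- setdiff(colnames(b), colnames(a))
  if (length(only_a) || length(only_b)) {
    msg <- paste0("samples not present in both fractions: ",
                  paste(c(only_a, only_b), collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; missing fraction treated as zeros")
  }
  asvs <- union(rownames(a), rownames(b))
  samples <- union(colnames(a), colnames(b))
  out <- matrix(0, length(asvs), length(samples), dimnames = list(asvs, samples))
  out[rownames(a), colnames(a)] <- out[rownames(a), colnames(a)] + a
  out[rownames(b), colnames(b)] <- out[rownames(b), colnames(b)] + b
  out
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (multivariate hypergeometric draw, delegated to [vegan::rrarefy()]).
#' Samples whose total is below `depth` are dropped with a message; a sample
#' with exactly `depth` reads is returned unchanged. The draw is fully
#' determined by `seed`.
#'
#' @param x count matrix.
#' @param depth target reads per sample (positive integer).
#' @param seed integer RNG seed (mandatory: rarefaction is a random draw).
#' @return rarefied count matrix whose retained columns each sum to `depth`.
#' @export
rarefy <- function(x, depth, seed) {
  x <- validate_count_table(x)
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) || depth <= 0 ||
      abs(depth - round(depth)) > 1e-8) {
    stop("`depth` must be a single positive integer")
  }
  if (missing(seed)) stop("`seed` is required for reproducible rarefaction")
  depth <- as.integer(round(depth))
  tot <- colSums(x)
  drop <- tot < depth
  if (any(drop)) {
    message(sum(drop), " sample(s) with fewer than ", depth, " reads dropped: ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no sample reaches rarefaction depth ", depth)
  # vegan heuristically warns whenever the smallest nonzero entry exceeds 1;
  # inputs here are validated integer counts, so that warning is noise
  out <- withr::with_seed(
    as.integer(seed),
    withCallingHandlers(
      t(vegan::rrarefy(t(x), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }))
  storage.mode(out) <- "double"
  dimnames(out) <- list(rownames(x), colnames(x))
  out
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each column by its total. All-zero samples are left at zero and
#' flagged in the `"zero_samples"` attribute (with a warning) rather than
#' divided.
#'
#' @param x count matrix.
#' @return matrix of proportions; non-flagged columns sum to 1.
#' @export
relative_abundance <- function(x) {
  x <- validate_count_table(x)
  tot <- colSums(x)
  zero <- tot == 0
  tot[zero] <- 1  # leave flagged columns untouched
  out <- sweep(x, 2L, tot, "/")
  if (any(zero)) {
    warning("all-zero sample(s) flagged, not normalised: ",
            paste(colnames(x)[zero], collapse = ", "))
  }
  attr(out, "zero_samples") <- colnames(x)[zero]
  out
}
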