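#' Spectral-count tables for bait-versus-control enrichment
#'
#' A `count_table` holds long-format MS/MS spectral counts from an
#' affinity-enrichment experiment: one row per (protein, block, condition)
#' cell, where a block is a biological replicate unit (here, an individual
#' animal) and condition 0 is the scrambled-peptide control pull-down,
#' condition 1 the bait-peptide pull-down.
#'
#' @param x data.frame with columns `protein_id`, `block_id`, `condition`,
#'   `count`. `condition` may be 0/1 or the labels "control"/"bait".
#' @param impute_missing if `TRUE`, missing (protein, block, condition)
#'   cells are filled with count 0 and flagged in the returned object;
#'   by default an incomplete design is an error.
#'
#' @return object of class `count_table`: the validated data.frame with
#'   attributes `proteins`, `blocks`, and `imputed_cells`.
#' @export
count_table <- function(x, impute_missing = FALSE) {
  need <- c("protein_id", "block_id", "condition", "count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x)[, need]
  x$protein_id <- as.character(x$protein_id)
  x$block_id <- as.character(x$block_id)
  x$condition <- normalize_condition(x$condition)
  x$count <- validate_counts(x$count)

  key <- paste(x$protein_id, x$block_id, x$condition, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (protein, block, condition) cell(s): ",
         paste(utils::head(gsub("\r", "/", key[dup]), 5L), collapse = "; "))
  }

  proteins <- sort(unique(x$protein_id))
  blocks <- sort(unique(x$block_id))
  if (length(proteins) < 2L) {
    stop("count table must contain at least 2 proteins")
  }
  if (!all(c(0L, 1L) %in% x$condition)) {
    stop("both conditions (0 = control, 1 = bait) must be present")
  }

  full <- expand.grid(protein_id = proteins, block_id = blocks,
                      condition = c(0L, 1L), stringsAsFactors = FALSE)
  full_key <- paste(full$protein_id, full$block_id, full$condition, sep = "\r")
  absent <- setdiff(full_key, key)
  imputed <- character(0)
  if (length(absent) > 0L) {
    if (!impute_missing) {
      stop("incomplete design; missing cell(s) (protein/block/condition): ",
           paste(utils::head(gsub("\r", "/", absent), 5L), collapse = "; "))
    }
    add <- full[full_key %in% absent, , drop = FALSE]
    add$count <- 0L
    x <- rbind(x, add)
    imputed <- gsub("\r", "/", absent)
  }

  x <- x[order(x$protein_id, x$block_id, x$condition), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("count_table", "data.frame"),
            proteins = proteins, blocks = blocks, imputed_cells = imputed)
}

normalize_condition <- function(cond) {
  if (is.character(cond) || is.factor(cond)) {
    cond <- tolower(trimws(as.character(cond)))
    map <- c("0" = 0L, "1" = 1L, "control" = 0L, "bait" = 1L,
             "scrambled" = 0L, "treated" = 1L)
    out <- unname(map[cond])
    if (anyNA(out)) {
      stop("unrecognized condition label(s): ",
           paste(unique(cond[is.na(out)]), collapse = ", "))
    }
    return(out)
  }
  cond <- as.numeric(cond)
  if (!all(cond %in% c(0, 1))) stop("condition must be 0 (control) or 1 (bait)")
  as.integer(cond)
}

validate_counts <- function(count) {
  if (is.character(count)) {
    num <- suppressWarnings(as.numeric(count))
    if (anyNA(num)) stop("non-numeric count value(s): ",
                         paste(unique(count[is.na(num)]), collapse = ", "))
    count <- num
  }
  count <- as.numeric(count)
  if (anyNA(count)) stop("missing count values")
  frac <- abs(count - round(count)) > 1e-8
  if (any(frac)) {
    stop("non-integer count value(s): ",
         paste(unique(count[frac]), collapse = ", "))
  }
  if (any(count < 0)) stop("negative count values")
  count <- round(count)
  # keep numeric storage beyond the integer range (extreme simulated rates)
  if (all(count <= .Machine$integer.max)) count <- as.integer(count)
  count
}

#' Read a spectral-count table from TSV/CSV
#'
#' Expects a header with columns `protein_id, block_id, condition, count`;
#' comma or tab separated, UTF-8. Condition labels 0/1 or control/bait.
#' Counts written as e.g. "3.0" are accepted (with a warning); fractional
#' counts are an error.
#'
#' @param path file path.
#' @param impute_missing passed to [count_table()].
#' @return a `count_table`.
#' @export
read_count_table <- function(path, impute_missing = FALSE) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  x <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         colClasses = list(character = "protein_id"))
  if (is.numeric(x$count) && any(abs(x$count - round(x$count)) <= 1e-8 &
                                 x$count != round(x$count) + 0)) {
    # e.g. "3.0" parsed as double; count_table() will round it
  }
  if (is.double(x$count) &&
      all(abs(x$count - round(x$count)) <= 1e-8)) {
    warning("counts parsed from decimal notation; rounding to integers")
  }
  count_table(x, impute_missing = impute_missing)
}

#' Per-block count matrices
#'
#' Reshapes a `count_table` into a pair of p-by-C integer matrices
#' (control and bait counts), rows sorted by protein, columns by block.
#'
#' @param table a `count_table`.
#' @return list with `y0`, `y1` (p x C matrices), `proteins`, `blocks`.
#' @keywords internal
count_arrays <- function(table) {
  stopifnot(inherits(table, "count_table"))
  proteins <- attr(table, "proteins")
  blocks <- attr(table, "blocks")
  p <- length(proteins); C <- length(blocks)
  gi <- match(table$protein_id, proteins)
  ci <- match(table$block_id, blocks)
  y0 <- matrix(NA_real_, p, C, dimnames = list(proteins, blocks))
  y1 <- y0
  is1 <- table$condition == 1L
  y0[cbind(gi[!is1], ci[!is1])] <- table$count[!is1]
  y1[cbind(gi[is1], ci[is1])] <- table$count[is1]
  if (anyNA(y0) || anyNA(y1)) stop("internal: incomplete design after validation")
  list(y0 = y0, y1 = y1, proteins = proteins, blocks = blocks)
}

#' Plug-in per-block scale factors
#'
#' Computes the fixed per-block scale mu_c as the across-protein mean of
#' the average pseudo-count-shifted spectral count in the two conditions,
#' mu_c = p^-1 * sum_g (y_gc0 + y_gc1 + 2 * pseudo_count) / 2.
#' These are plugged into the count model and never resampled.
#'
#' @param table a `count_table`.
#' @param pseudo_count integer offset added to each count inside the
#'   likelihood (default 1).
#' @return named numeric vector, one strictly positive value per block.
#' @export
compute_mu_plugin <- function(table, pseudo_count = 1) {
  a <- count_arrays(table)
  mu <- colMeans((a$y0 + a$y1 + 2 * pseudo_count) / 2)
  if (any(mu <= 0)) stop("plug-in mu_c must be strictly positive; ",
                         "use a positive pseudo_count with all-zero counts")
  mu
}
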