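#' Regulatory-interaction table
#'
#' A signed edge list of regulator-to-target interactions, the structure
#' used by curated regulatory-network compilations. Duplicate edges are
#' collapsed; a regulator-target pair recorded both as repression and as
#' activation is reconciled to sign `"dual"`.
#'
#' @param regulator_id,target_id character vectors of equal length
#'   (non-empty strings).
#' @param sign character vector with values among `"repression"`,
#'   `"activation"`, `"dual"`, `"unknown"`.
#' @return data.frame of class `nar_census_table` with columns
#'   `regulator_id`, `target_id`, `sign`.
#' @examples
#' census_table(c("tfA", "tfA", "tfB"), c("tfA", "tfB", "tfB"),
#'              c("repression", "activation", "activation"))
#' @export
census_table <- function(regulator_id, target_id, sign) {
  regulator_id <- as.character(regulator_id)
  target_id <- as.character(target_id)
  sign <- as.character(sign)
  if (length(regulator_id) != length(target_id) ||
      length(sign) != length(target_id))
    stop("columns must have equal length", call. = FALSE)
  if (any(!nzchar(regulator_id)) || any(!nzchar(target_id)))
    stop("ids must be non-empty strings", call. = FALSE)
  ok <- c("repression", "activation", "dual", "unknown")
  if (!all(sign %in% ok))
    stop("'sign' must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  if (length(sign) == 0L) {
    out <- data.frame(regulator_id = character(0), target_id = character(0),
                      sign = character(0), stringsAsFactors = FALSE)
    class(out) <- c("nar_census_table", "data.frame")
    return(out)
  }
  tab <- data.frame(regulator_id = regulator_id, target_id = target_id,
                    sign = sign, stringsAsFactors = FALSE)
  # collapse duplicates with sign reconciliation
  key <- paste(tab$regulator_id, tab$target_id, sep = "\r")
  signs <- split(tab$sign, key)
  recon <- vapply(signs, function(s) {
    s <- unique(s)
    if ("dual" %in% s || all(c("repression", "activation") %in% s)) "dual"
    else if ("repression" %in% s) "repression"
    else if ("activation" %in% s) "activation"
    else "unknown"
  }, character(1))
  parts <- do.call(rbind, strsplit(names(recon), "\r", fixed = TRUE))
  out <- data.frame(regulator_id = parts[, 1], target_id = parts[, 2],
                    sign = unname(recon), stringsAsFactors = FALSE)
  out <- out[order(out$regulator_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nar_census_table", "data.frame")
  out
}

#' Generate a synthetic regulatory-interaction table
#'
#' Synthetic stand-in for curated regulatory-network tables, with
#' controllable autoregulation and repressor proportions. Each of `n_tf`
#' transcription factors independently negatively autoregulates with
#' probability `p_neg_auto` or positively with `p_pos_auto` (mutually
#' exclusive; a self-edge of the corresponding sign is emitted). Repressive
#' function overall occurs with probability `p_repressor`: negative
#' autoregulators are repressors by construction (their self-edge
#' represses); among the remaining factors, enough are assigned repressive
#' target edges to make the expected repressor fraction `p_repressor`
#' (requires `p_repressor >= p_neg_auto`). Every factor additionally
#' regulates `edges_per_tf` random other factors.
#'
#' @param n_tf number of transcription factors.
#' @param p_neg_auto,p_pos_auto autoregulation probabilities
#'   (`p_neg_auto + p_pos_auto <= 1`).
#' @param p_repressor overall probability of repressive function
#'   (`>= p_neg_auto`).
#' @param edges_per_tf number of non-self regulatory edges per factor.
#' @param seed RNG seed.
#' @return An `nar_census_table`.
#' @examples
#' tab <- generate_census_table(182, p_neg_auto = 82 / 182, seed = 1)
#' census(tab)
#' @export
generate_census_table <- function(n_tf, p_neg_auto, p_pos_auto = 0.05,
                                  p_repressor = max(0.5, p_neg_auto),
                                  edges_per_tf = 2L, seed = 1L) {
  if (any(c(p_neg_auto, p_pos_auto, p_repressor) < 0) ||
      any(c(p_neg_auto, p_pos_auto, p_repressor) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p_neg_auto + p_pos_auto > 1)
    stop("'p_neg_auto' + 'p_pos_auto' must be <= 1", call. = FALSE)
  if (p_repressor < p_neg_auto)
    stop("'p_repressor' must be >= 'p_neg_auto' (negative autoregulators ",
         "are repressors)", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ids <- sprintf("tf%03d", seq_len(n_tf))
  u <- runif(n_tf)
  auto <- ifelse(u < p_neg_auto, "repression",
                 ifelse(u < p_neg_auto + p_pos_auto, "activation", "none"))
  # conditional probability of repressive target edges among non-negautoreg
  p_extra <- if (p_neg_auto < 1)
    (p_repressor - p_neg_auto) / (1 - p_neg_auto) else 0
  extra_rep <- auto != "repression" & runif(n_tf) < p_extra
  reg <- tar <- sgn <- character(0)
  for (i in seq_len(n_tf)) {
    if (auto[i] != "none") {
      reg <- c(reg, ids[i]); tar <- c(tar, ids[i]); sgn <- c(sgn, auto[i])
    }
    k <- min(edges_per_tf, n_tf - 1L)
    if (k > 0) {
      tg <- sample(ids[-i], k)
      s <- if (extra_rep[i]) c("repression",
                               sample(c("repression", "activation"),
                                      k - 1L, replace = TRUE))
           else rep("activation", k)
      reg <- c(reg, rep(ids[i], k)); tar <- c(tar, tg); sgn <- c(sgn, s)
    }
  }
  tab <- census_table(reg, tar, sgn)
  attr(tab, "n_tf") <- as.integer(n_tf)
  attr(tab, "tf_ids") <- ids
  tab
}

#' Autoregulation census of a regulatory table
#'
#' Counts autoregulation motifs: a regulator is a negative (positive)
#' autoregulator iff it has a self-edge with sign repression (activation);
#' `"dual"` self-edges count as both. A regulator is a repressor iff it has
#' at least one repression or dual edge to any target (itself included).
#' Fractions are reported over all regulators and, for negative
#' autoregulation, additionally over repressors only — the restriction that
#' controls for a general under-representation of repressive function.
#'
#' @param table an `nar_census_table` (or data.frame with the same
#'   columns).
#' @param n_tf total number of transcription factors the table describes;
#'   defaults to the table's `n_tf` attribute or, failing that, the number
#'   of distinct regulator ids.
#' @return Object of class `nar_census_summary`: list with counts `n_tf`,
#'   `n_neg_auto`, `n_pos_auto`, `n_repressors`, `n_neg_auto_repressors`
#'   and the fractions `frac_neg_auto`, `frac_pos_auto`,
#'   `frac_neg_auto_of_repressors`.
#' @examples
#' tab <- census_table(c("a", "a", "b"), c("a", "b", "a"),
#'                     c("repression", "activation", "repression"))
#' census(tab)
#' @export
census <- function(table, n_tf = NULL) {
  if (!all(c("regulator_id", "target_id", "sign") %in% names(table)))
    stop("table must have columns regulator_id, target_id, sign",
         call. = FALSE)
  if (!inherits(table, "nar_census_table"))
    table <- census_table(table$regulator_id, table$target_id, table$sign)
  if (is.null(n_tf))
    n_tf <- attr(table, "n_tf") %||% length(unique(table$regulator_id))
  if (nrow(table) == 0) {
    out <- list(n_tf = 0L, n_neg_auto = 0L, n_pos_auto = 0L,
                n_repressors = 0L, n_neg_auto_repressors = 0L,
                frac_neg_auto = NA_real_, frac_pos_auto = NA_real_,
                frac_neg_auto_of_repressors = NA_real_)
    return(structure(out, class = "nar_census_summary"))
  }
  self <- table[table$regulator_id == table$target_id, , drop = FALSE]
  neg_auto <- unique(self$regulator_id[self$sign %in% c("repression", "dual")])
  pos_auto <- unique(self$regulator_id[self$sign %in% c("activation", "dual")])
  repressors <- unique(table$regulator_id[table$sign %in%
                                            c("repression", "dual")])
  out <- list(n_tf = as.integer(n_tf),
              n_neg_auto = length(neg_auto),
              n_pos_auto = length(pos_auto),
              n_repressors = length(repressors),
              n_neg_auto_repressors = length(intersect(neg_auto, repressors)),
              frac_neg_auto = length(neg_auto) / n_tf,
              frac_pos_auto = length(pos_auto) / n_tf,
              frac_neg_auto_of_repressors =
                if (length(repressors))
                  length(intersect(neg_auto, repressors)) / length(repressors)
                else NA_real_)
  structure(out, class = "nar_census_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nar_census_summary <- function(x, ...) {
  cat(sprintf(paste0("<nar_census_summary> %d TFs: %d negative / %d positive ",
                     "autoregulators (%.1f%% / %.1f%%)\n  %d repressors; ",
                     "negative autoregulation among repressors: %d (%.1f%%)\n"),
              x$n_tf, x$n_neg_auto, x$n_pos_auto, 100 * x$frac_neg_auto,
              100 * x$frac_pos_auto, x$n_repressors, x$n_neg_auto_repressors,
              100 * x$frac_neg_auto_of_repressors))
  invisible(x)
}

#' Read/write regulatory tables as TSV
#'
#' TSV with header `regulator_id`, `target_id`, `sign` — the schema used
#' for user-supplied curated tables.
#'
#' @param path file path.
#' @param table an `nar_census_table`.
#' @return `read_census_table()` returns an `nar_census_table`;
#'   `write_census_table()` returns `path` invisibly.
#' @export
read_census_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  census_table(df$regulator_id, df$target_id, df$sign)
}

#' @rdname read_census_table
#' @export
write_census_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
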