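#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term_id <TAB> description <TAB> member1 <TAB> member2 ...`. Members are
#' uppercased and deduplicated; terms with fewer than `min_size` members
#' after cleaning are dropped with a message.
#'
#' @param path Path to a GMT file.
#' @param namespace Label for the collection (e.g. `"BP"`, `"pathway"`).
#' @param min_size Minimum member count for a term to be kept (default 3).
#' @return A `gene_set_collection`: list with `namespace` and `terms`
#'   (named list of member character vectors, names = term ids) and
#'   `term_names` (descriptions).
#' @export
read_gmt <- function(path, namespace = "geneset", min_size = 3) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT row ", short[1], " has fewer than 3 tab-separated fields",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated term id in GMT: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  descs <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) normalize_symbols(f[-(1:2)]))
  keep <- lengths(members) >= min_size
  if (any(!keep)) {
    message("dropped ", sum(!keep), " term(s) with < ", min_size, " members")
  }
  gene_set_collection(stats::setNames(members[keep], ids[keep]),
                      namespace = namespace,
                      term_names = stats::setNames(descs[keep], ids[keep]))
}

#' Construct a gene-set collection in memory
#'
#' @param terms Named list of member character vectors (names = term ids).
#' @param namespace Collection label.
#' @param term_names Optional named character vector of descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(terms, namespace = "geneset",
                                term_names = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)),
            !anyDuplicated(names(terms)))
  if (any(lengths(terms) == 0L)) stop("empty member set in collection",
                                      call. = FALSE)
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  }
  structure(list(namespace = namespace, terms = terms,
                 term_names = term_names),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", x$namespace, ": ", length(x$terms),
      " terms, median size ", stats::median(lengths(x$terms)), "\n", sep = "")
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts the overlap between a random draw of size n
#' from a universe of N genes and a term of K genes:
#' sum over i = k..min(K, n) of C(K,i) C(N-K, n-i) / C(N, n).
#' Computed in log space from scratch; k = 0 returns exactly 1.
#'
#' @param k Observed overlap.
#' @param K Term size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return The tail probability in (0, 1].
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 0, n <= N, k >= 0)
  if (k == 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  p <- sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min_{j >= i} ( p_(j) * m / j ), capped at 1, returned in the
#' input order.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Over-representation analysis of a query gene set
#'
#' For every term in the collection, tests whether the query set overlaps
#' the term more than expected under hypergeometric sampling from the
#' universe. The default universe is the set of all genes annotated
#' anywhere in the collection (the common convention when no assay
#' background is stated); it is echoed in a message. Query symbols outside
#' the universe are dropped with a message. Terms with zero overlap are
#' reported with p = 1. Q-values are Benjamini-Hochberg adjusted across all
#' tested terms of the collection.
#'
#' @param query Character vector of gene symbols (uppercased internally).
#' @param collection A `gene_set_collection`.
#' @param universe Optional character vector defining the background;
#'   default: all symbols annotated in the collection.
#' @return A data frame, one row per term: `term_id`, `term_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, `fold_enrichment`, `hits`
#'   (semicolon-joined overlap symbols).
#' @export
ora <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- normalize_symbols(query)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(collection$terms)))
    message("universe defaulted to all ", length(universe),
            " annotated symbols in collection '", collection$namespace, "'")
  } else {
    universe <- normalize_symbols(universe)
  }
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message("dropped ", length(outside), " query symbol(s) not in universe")
  }
  query <- intersect(query, universe)
  if (length(query) == 0L) {
    stop("query is empty after universe restriction", call. = FALSE)
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection$terms), function(id) {
    members <- intersect(collection$terms[[id]], universe)
    K <- length(members)
    hits <- intersect(members, query)
    k <- length(hits)
    p <- hyper_upper_tail(k, K, n, N)
    fold <- if (K > 0) (k / n) / (K / N) else 0
    data.frame(term_id = id,
               term_name = unname(collection$term_names[id]),
               k = k, K = K, n = n, N = N,
               p_value = p, q_value = NA_real_,
               fold_enrichment = fold,
               hits = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Filter and rank enrichment results
#'
#' Keeps terms with q-value below `alpha`, sorts by ascending p-value and
#' truncates to the top `n`.
#'
#' @param results Data frame from [ora()].
#' @param n Maximum number of rows returned (default 10).
#' @param alpha Significance cut-off on the adjusted p-value (default 0.05).
#' @return The filtered, sorted, truncated data frame.
#' @export
top_terms <- function(results, n = 10, alpha = 0.05) {
  stopifnot(n >= 1)
  sig <- results[results$q_value < alpha, , drop = FALSE]
  sig <- sig[order(sig$p_value), , drop = FALSE]
  utils::head(sig, n)
}
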