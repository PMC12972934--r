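#' Read a docking-result table
#'
#' CSV with one row per target and a binding-energy column in kcal/mol
#' (more negative = stronger predicted binding). Column names are matched
#' case-insensitively; the energy column is the first of `binding_energy`,
#' `energy`, or any column whose name contains "energy".
#'
#' @param path CSV path.
#' @return Data frame `target`, `binding_energy` (plus `component` if
#'   present). Duplicate targets and non-numeric energies are errors.
#' @export
read_docking_table <- function(path) {
  if (!file.exists(path)) stop("docking table not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("docking table is empty", call. = FALSE)
  lc <- tolower(names(df))
  tcol <- which(lc == "target")[1]
  ecol <- which(lc %in% c("binding_energy", "energy"))[1]
  if (is.na(ecol)) ecol <- grep("energy", lc)[1]
  if (is.na(tcol) || is.na(ecol)) {
    stop("docking table needs 'target' and an energy column", call. = FALSE)
  }
  energy <- suppressWarnings(as.numeric(df[[ecol]]))
  if (anyNA(energy)) {
    stop("non-numeric binding energy in row ", which(is.na(energy))[1],
         call. = FALSE)
  }
  target <- toupper(trimws(as.character(df[[tcol]])))
  if (anyDuplicated(target)) {
    stop("duplicate target in docking table: ",
         target[duplicated(target)][1], call. = FALSE)
  }
  out <- data.frame(target = target, binding_energy = energy,
                    stringsAsFactors = FALSE)
  ccol <- which(lc == "component")[1]
  if (!is.na(ccol)) out$component <- as.character(df[[ccol]])
  out
}

#' Summary statistics of a docking table
#'
#' @param table Data frame from [read_docking_table()].
#' @param bound Energy bound in kcal/mol; rows at or below it (i.e. at
#'   least as strongly bound) are counted. Default -4.3.
#' @return List `min` (most negative), `max` (least negative), `mean`,
#'   `n_at_or_below_bound`, `bound`.
#' @export
docking_summary <- function(table, bound = -4.3) {
  if (nrow(table) == 0L) stop("empty docking table", call. = FALSE)
  e <- table$binding_energy
  list(min = min(e), max = max(e), mean = mean(e),
       n_at_or_below_bound = sum(e <= bound), bound = bound)
}

#' Rank docking targets by binding energy
#'
#' Competition ranking ("1224"): ascending energy (most negative = rank 1);
#' tied energies share the better rank and the next rank is skipped.
#'
#' @param table Data frame from [read_docking_table()].
#' @return Named integer vector of ranks, names = targets.
#' @export
rank_by_energy <- function(table) {
  if (nrow(table) == 0L) stop("empty docking table", call. = FALSE)
  stats::setNames(rank(table$binding_energy, ties.method = "min"),
                  table$target)
}

#' Fuse evidence channels into one priority ordering
#'
#' Combines per-channel target rankings (e.g. MCC rank, docking-energy
#' rank, machine-learning score rank) by Borda rank-sum: the aggregate
#' score of a target is the sum of its channel ranks and the final ranking
#' is ascending on that sum (competition ranking). A target missing from a
#' channel carries the worst-rank penalty n+1 for that channel (n = number
#' of targets ranked in the channel) and is flagged. `"mean-rank"` divides
#' the sum by the number of channels, which leaves the ordering unchanged.
#'
#' @param channels Named list of named rank vectors (1 = best).
#' @param method `"borda"` (rank sum, default) or `"mean-rank"`.
#' @return Data frame with one `<channel>_rank` column per channel,
#'   `n_missing`, `aggregate_score`, `final_rank`, sorted by `final_rank`.
#' @export
aggregate_ranks <- function(channels, method = c("borda", "mean-rank")) {
  method <- match.arg(method)
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  targets <- sort(unique(unlist(lapply(channels, names))))
  if (length(targets) == 0L) stop("no targets in any channel", call. = FALSE)
  rank_mat <- sapply(channels, function(ch) {
    penalty <- length(ch) + 1
    r <- ch[targets]
    r[is.na(r)] <- penalty
    r
  })
  rank_mat <- matrix(rank_mat, nrow = length(targets),
                     dimnames = list(targets, names(channels)))
  missing_mat <- sapply(channels, function(ch) !(targets %in% names(ch)))
  missing_mat <- matrix(missing_mat, nrow = length(targets))
  agg <- rowSums(rank_mat)
  if (method == "mean-rank") agg <- agg / length(channels)
  final <- rank(agg, ties.method = "min")
  out <- data.frame(target = targets, rank_mat,
                    n_missing = rowSums(missing_mat),
                    aggregate_score = agg, final_rank = final,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[seq_along(channels) + 1L] <- paste0(names(channels), "_rank")
  out[order(out$final_rank, out$target), , drop = FALSE]
}
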