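# From per-node ancestral ranges to dated dispersal/extinction scenarios:
# best range per node, per-branch event inference, time-slice summaries and
# events-through-time histograms.

#' Best range per node
#'
#' The range with the highest relative probability at each internal node,
#' with a deterministic tie-break (fewest areas, then lowest bit value);
#' ties are flagged. Tips carry their observed range with probability 1.
#'
#' @param table An `rd_ranges` tibble from [ancestral_range_marginals()].
#' @param tree The chronogram the table was computed on.
#' @param tip_ranges Tibble `species`/`range` of observed tip ranges.
#' @param areas Area codebook (used for the canonical tie-break order).
#' @return A tibble with one row per node (internal and tips): `node`,
#'   `age`, `range`, `prob`, `tie`, `is_tip`.
#' @export
best_range_per_node <- function(table, tree, tip_ranges,
                                areas = default_areas()) {
  nt <- ape::Ntip(tree)
  internal <- (nt + 1):(nt + tree$Nnode)
  missing <- setdiff(internal, unique(table$node))
  if (length(missing) > 0) {
    stop("ancestral-range table misses node(s): ",
         paste(missing, collapse = ", "))
  }
  bits <- range_bits(table$range, areas)
  tb <- tibble::tibble(node = table$node, age = table$age,
                       range = table$range, prob = table$prob,
                       .size = bit_count(bits), .bits = bits)
  picks <- tb |>
    dplyr::group_by(.data$node) |>
    dplyr::group_modify(function(df, key) {
      mx <- max(df$prob)
      cand <- df[df$prob >= mx - 1e-12, , drop = FALSE]
      cand <- cand[order(cand$.size, cand$.bits), , drop = FALSE]
      tibble::tibble(age = cand$age[1], range = cand$range[1],
                     prob = cand$prob[1], tie = nrow(cand) > 1)
    }) |>
    dplyr::ungroup()
  picks$is_tip <- FALSE
  labs <- normalize_names(tree$tip.label)
  idx <- match(labs, normalize_names(tip_ranges$species))
  if (anyNA(idx)) {
    stop("tips missing from the range table: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  ages <- node_ages(tree)
  tips <- tibble::tibble(node = seq_len(nt), age = ages[seq_len(nt)],
                         range = tip_ranges$range[idx], prob = 1,
                         tie = FALSE, is_tip = TRUE)
  dplyr::bind_rows(tips, picks) |> dplyr::arrange(.data$node)
}

# For a parent best range and the two daughters' best ranges, the
# cladogenetic outcome (ordered daughter pair) minimising the total
# symmetric difference to the observed daughters; canonical tie-break.
best_clado_outcome <- function(parent_bits, d1_bits, d2_bits, space) {
  pr <- clado_pairs(parent_bits, length(space$areas))
  keep <- !is.na(state_index(space, pr$left)) &
    !is.na(state_index(space, pr$right))
  pr <- pr[keep, , drop = FALSE]
  cost <- bit_count(bitwXor(pr$left, d1_bits)) +
    bit_count(bitwXor(pr$right, d2_bits))
  ord <- order(cost, bit_count(pr$left), pr$left, pr$right)
  pr[ord[1], , drop = FALSE]
}

#' Infer biogeographic events along one branch
#'
#' Compares a baseline range at the top of a branch with the range at its
#' bottom and emits one dispersal per gained area and one extinction per
#' lost area (the single-area steps permitted by the DEC rate matrix).
#' Event times are placed at quantiles `k/(m+1)` of the branch interval for
#' `m` events, oldest first; extinctions are assigned the oldest times, then
#' dispersals.
#'
#' @param parent_range,child_range Range labels at the branch top/bottom.
#' @param parent_age,child_age Branch endpoint ages (Ma).
#' @param source_range Label recorded as the dispersal source (defaults to
#'   `parent_range`).
#' @param areas Area codebook.
#' @return A tibble with columns `kind` (`"dispersal"`/`"extinction"`),
#'   `area`, `source`, `time`; empty when the ranges are equal.
#' @export
infer_branch_events <- function(parent_range, child_range,
                                parent_age, child_age,
                                source_range = parent_range,
                                areas = default_areas()) {
  codes <- area_codes(areas)
  pb <- range_bits(parent_range, codes)
  cb <- range_bits(child_range, codes)
  gained <- bits_areas_idx(bitwAnd(cb, bitwNot(pb)), length(codes))
  lost <- bits_areas_idx(bitwAnd(pb, bitwNot(cb)), length(codes))
  m <- length(gained) + length(lost)
  if (m == 0) {
    return(tibble::tibble(kind = character(0), area = character(0),
                          source = character(0), time = numeric(0)))
  }
  times <- parent_age - seq_len(m) * (parent_age - child_age) / (m + 1)
  tibble::tibble(
    kind = c(rep("extinction", length(lost)), rep("dispersal", length(gained))),
    area = codes[c(lost, gained)],
    source = c(rep(NA_character_, length(lost)), rep(source_range,
                                                     length(gained))),
    time = times)
}

#' Infer the dispersal/extinction scenario on a whole tree
#'
#' Walks every branch of the tree, comparing each child's best range to a
#' baseline derived from its parent's best range. With
#' `cladogenesis_aware = TRUE` (default) the parent range is first passed
#' through the cladogenetic outcome best matching the two daughters' ranges
#' (DEC changes ranges at nodes too; a raw node-vs-node diff inflates
#' events); with `FALSE` the raw parent range is the baseline.
#'
#' @param best A tibble from [best_range_per_node()].
#' @param tree The chronogram.
#' @param space A `dec_space` (constrains which inherited ranges exist).
#' @param cladogenesis_aware Logical, see above.
#' @return A tibble (class `rd_events`) with columns `kind`, `area`,
#'   `source`, `time`, `parent`, `child`, `from_root`; attribute `baseline`
#'   records the comparison mode, attribute `root_age` the crown age.
#' @export
infer_scenario <- function(best, tree, space = dec_state_space(),
                           cladogenesis_aware = TRUE) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  ch <- children_of(tree, strict = TRUE)
  rng <- stats::setNames(best$range, best$node)
  age <- stats::setNames(best$age, best$node)
  rows <- list()
  for (v in (nt + 1):(nt + tree$Nnode)) {
    pb <- range_bits(rng[[as.character(v)]], space$areas)
    c1 <- ch[v, 1]; c2 <- ch[v, 2]
    if (cladogenesis_aware) {
      d1 <- range_bits(rng[[as.character(c1)]], space$areas)
      d2 <- range_bits(rng[[as.character(c2)]], space$areas)
      out <- best_clado_outcome(pb, d1, d2, space)
      base1 <- range_label(out$left, space$areas)
      base2 <- range_label(out$right, space$areas)
    } else {
      base1 <- base2 <- range_label(pb, space$areas)
    }
    for (k in 1:2) {
      cc <- if (k == 1) c1 else c2
      bb <- if (k == 1) base1 else base2
      ev <- infer_branch_events(bb, rng[[as.character(cc)]],
                                age[[as.character(v)]],
                                age[[as.character(cc)]],
                                source_range = bb, areas = space$areas)
      if (nrow(ev) > 0) {
        ev$parent <- v; ev$child <- cc; ev$from_root <- v == root
        rows[[length(rows) + 1]] <- ev
      }
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(kind = character(0), area = character(0),
                   source = character(0), time = numeric(0),
                   parent = integer(0), child = integer(0),
                   from_root = logical(0))
  attr(out, "baseline") <- if (cladogenesis_aware) "cladogenesis-aware"
    else "raw parent range"
  attr(out, "root_age") <- max(node_ages(tree))
  class(out) <- c("rd_events", class(out))
  out
}

#' Two-slice summary of biogeographic events
#'
#' Splits events at a time boundary (default 16 Ma, the Mid-Miocene
#' Climatic Optimum) and tabulates, per slice, directed dispersal counts by
#' (source area, recipient area) pair and extinction counts per area.
#' Multi-area dispersal sources are attributed fractionally (1/|source| per
#' source area) so totals are conserved.
#'
#' @param events An `rd_events` tibble (or compatible).
#' @param boundary Slice boundary in Ma (events with `time > boundary` fall
#'   in slice 1).
#' @param exclude_root Drop events on the root's own branches (the deepest
#'   reconstruction is usually not interpretable without outgroup sampling).
#' @param areas Area codebook.
#' @return A list of class `rd_slices`: `dispersal` (tibble `slice`,
#'   `from`, `to`, `count`), `extinction` (tibble `slice`, `area`, `count`),
#'   `totals` (per-slice dispersal/extinction totals) and `boundary`.
#' @export
summarize_time_slices <- function(events, boundary = 16,
                                  exclude_root = TRUE,
                                  areas = default_areas()) {
  codes <- area_codes(areas)
  ev <- tibble::as_tibble(events)
  if (exclude_root && "from_root" %in% names(ev)) {
    ev <- ev[!ev$from_root, , drop = FALSE]
  }
  ev$slice <- ifelse(ev$time > boundary, 1L, 2L)
  disp <- ev[ev$kind == "dispersal", , drop = FALSE]
  drows <- list()
  if (nrow(disp) > 0) {
    for (i in seq_len(nrow(disp))) {
      src <- bits_areas_idx(range_bits(disp$source[i], codes), length(codes))
      w <- 1 / length(src)
      drows[[i]] <- tibble::tibble(slice = disp$slice[i],
                                   from = codes[src], to = disp$area[i],
                                   count = w)
    }
  }
  dispersal <- if (length(drows) > 0) {
    dplyr::bind_rows(drows) |>
      dplyr::group_by(.data$slice, .data$from, .data$to) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  } else tibble::tibble(slice = integer(0), from = character(0),
                        to = character(0), count = numeric(0))
  ext <- ev[ev$kind == "extinction", , drop = FALSE]
  extinction <- if (nrow(ext) > 0) {
    ext |>
      dplyr::group_by(.data$slice, area = .data$area) |>
      dplyr::summarise(count = dplyr::n(), .groups = "drop")
  } else tibble::tibble(slice = integer(0), area = character(0),
                        count = integer(0))
  totals <- tibble::tibble(
    slice = c(1L, 2L),
    dispersals = vapply(1:2, function(s) sum(disp$slice == s), numeric(1)),
    extinctions = vapply(1:2, function(s) sum(ext$slice == s), numeric(1)))
  structure(list(dispersal = dispersal, extinction = extinction,
                 totals = totals, boundary = boundary),
            class = "rd_slices")
}

#' @exportS3Method base::print
print.rd_slices <- function(x, ...) {
  cat("Biogeographic events in two time slices (boundary ", x$boundary,
      " Ma)\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Events-through-time histogram
#'
#' Bins dated events into uniform age bins over `[0, root_age]`.
#'
#' @param events An `rd_events` tibble.
#' @param bin_width Bin width in Myr (default 1).
#' @param root_age Upper end of the binned interval; defaults to the
#'   `root_age` attribute of `events`.
#' @return A tibble (class `rd_timeline`) with columns `bin_start` (older
#'   edge, Ma), `bin_end`, `dispersals`, `extinctions`.
#' @export
events_through_time <- function(events, bin_width = 1, root_age = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(root_age)) root_age <- attr(events, "root_age")
  if (is.null(root_age)) root_age <- max(c(events$time, bin_width))
  edges <- seq(0, root_age + bin_width, by = bin_width)
  mids <- function(kind) {
    t <- events$time[events$kind == kind]
    if (length(t) == 0) return(integer(length(edges) - 1))
    tabulate(findInterval(t, edges, rightmost.closed = TRUE),
             nbins = length(edges) - 1)
  }
  out <- tibble::tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
                        dispersals = mids("dispersal"),
                        extinctions = mids("extinction"))
  class(out) <- c("rd_timeline", class(out))
  out
}
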