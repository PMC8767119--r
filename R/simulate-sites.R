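# miRNA set generation and planting of duplex sites / hairpin copies.

#' Simulate mature miRNAs and hairpin references
#'
#' Mature lengths are drawn from 20-24 nt with mode 21; hairpins are random
#' references of 80-120 nt standing in for a curated database and are
#' labelled synthetic.
#'
#' @param config A [simulation_config].
#' @return list with `mirnas` and `hairpins`, both named character vectors.
#' @export
simulate_mirnas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  lens <- sample(20:24, config$n_mirnas, replace = TRUE,
                 prob = c(0.10, 0.45, 0.15, 0.05, 0.25))
  mirnas <- stats::setNames(vapply(lens, rand_dna, ""),
                            sprintf("mir_%03d", seq_len(config$n_mirnas)))
  hlens <- rint(config$n_hairpins, 80L, 120L)
  hairpins <- stats::setNames(vapply(hlens, rand_dna, ""),
                              sprintf("hairpin_%02d", seq_len(config$n_hairpins)))
  list(mirnas = mirnas, hairpins = hairpins)
}

WC_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# wobble partner on the target side: miRNA G pairs target T (RNA U),
# miRNA T pairs target G; A and C have no wobble partner
wobble_partner <- c(G = "T", T = "G", A = NA, C = NA)

# penalty accounting independent of the duplex engine: expectation of one
# planned edit list (positions on the miRNA, classes GU/MM) plus bulge
planned_expectation <- function(L, gu_pos = integer(), mm_pos = integer(),
                                bulge_len = 0L, bulge_after = 0L) {
  w <- function(i) ifelse(i >= 2 & i <= 13, 2, 1)
  e <- sum(0.5 * w(gu_pos)) + sum(1 * w(mm_pos))
  if (bulge_len > 0L) e <- e + 0.5 * bulge_len * w(bulge_after)
  e
}

# construct a binding-site string (5'->3' on the target) for one miRNA and
# one rule class; returns the site plus its planned annotation
make_site <- function(mirna, class) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  L <- length(m)
  tp <- unname(WC_COMP[m])          # target partner per miRNA position
  gu_pos <- integer(); mm_pos <- integer()
  bulge_len <- 0L; bulge_after <- 0L
  place_gu <- function(k, from) {
    # first k positions in 'from' where the miRNA nt supports a wobble
    cand <- from[m[from] %in% c("G", "T")]
    utils::head(cand, k)
  }
  tail_pos <- if (L >= 14L) 14:L else integer(0)
  if (class %in% c("target", "target_mrna")) {
    gu <- place_gu(1L, c(1L, tail_pos))
    if (length(gu)) {
      gu_pos <- gu
      tp[gu] <- wobble_partner[m[gu]]
    } else {
      mm_pos <- utils::tail(tail_pos, 1L)
      tp[mm_pos] <- m[mm_pos]
    }
  } else if (class == "etm") {
    bulge_len <- 3L; bulge_after <- 10L
    gu_pos <- place_gu(2L, tail_pos)
    tp[gu_pos] <- wobble_partner[m[gu_pos]]
  } else if (class == "near_miss_seed") {
    bulge_len <- 3L; bulge_after <- 10L
    gu_pos <- place_gu(2L, tail_pos)
    tp[gu_pos] <- wobble_partner[m[gu_pos]]
    mm_pos <- 5L
    tp[5L] <- m[5L]
  } else if (class == "near_miss_budget") {
    mm_pos <- 9:12
    tp[mm_pos] <- m[mm_pos]
  } else if (class == "near_miss_bulge") {
    bulge_len <- 3L; bulge_after <- 5L
  } else {
    stop("unknown site class: ", class)
  }
  bulge_nts <- if (class == "near_miss_bulge") {
    # adversarial bulge: copying the miRNA nucleotides guarantees that no
    # alternative alignment treating these as paired positions (the only
    # way to move the bulge into the permitted 9-12 window) can keep the
    # seed perfect, so the planted violation cannot be rescued
    m[bulge_after + seq_len(bulge_len)]
  } else {
    c("A", "C", "G", "T")[rint(bulge_len, 1L, 4L)]
  }
  in_mirna_order <- if (bulge_len > 0L) {
    c(tp[seq_len(bulge_after)], bulge_nts, tp[(bulge_after + 1L):L])
  } else tp
  site <- paste(rev(in_mirna_order), collapse = "")
  list(site = site,
       expected_expectation = planned_expectation(L, gu_pos, mm_pos,
                                                  bulge_len, bulge_after),
       expected_mm_gu = length(gu_pos) + length(mm_pos),
       bulge_len = bulge_len, bulge_after = bulge_after,
       seed_perfect = !any(mm_pos %in% 2:8) && !any(gu_pos %in% 2:8))
}

# simple per-host interval allocator avoiding previously used windows
allocate_window <- function(occupied, host, width, region, min_gap = 5L) {
  lo <- region[1]; hi <- region[2] - width
  if (hi < lo) return(NULL)
  used <- occupied[[host]]
  for (try in seq_len(200L)) {
    s <- rint(1L, lo, hi)
    e <- s + width
    clash <- FALSE
    if (!is.null(used) && nrow(used)) {
      clash <- any(used$start < e + min_gap & s < used$end + min_gap)
    }
    if (!clash) {
      occupied[[host]] <- rbind(used, data.frame(start = s, end = e))
      return(list(start = s, end = e, occupied = occupied))
    }
  }
  NULL
}

#' Plant miRNA binding sites of each rule class into sequences
#'
#' Edits host sequences in place (same-length window overwrite, so lengths
#' are preserved) and records every planted interaction with its rule class:
#' `target` / `target_mrna` (expectation <= 3), `etm` (all three mimic
#' criteria), `near_miss_seed` (one mismatch at miRNA position 5),
#' `near_miss_budget` (four mismatches outside the seed), `near_miss_bulge`
#' (3-nt bulge after position 5). miRNAs are assigned round-robin; window
#' positions avoid previously planted windows.
#'
#' @param seqs Named character vector of host sequences.
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param n_per_class Named integer vector of planted counts per rule class
#'   (names as above; classes may be omitted).
#' @param hosts Host ids to cycle over (default all of `seqs`).
#' @param allowed_regions Optional named list of `c(start, end)` 0-based
#'   half-open windows within which planting is allowed per host (defaults
#'   to the full sequence).
#' @param occupied Optional allocator state from a previous planting call.
#' @return list with `seqs` (edited), `truth_sites` (host, miRNA, class,
#'   0-based window, expected expectation and mismatch budget) and
#'   `occupied` (allocator state for chained planting).
#' @export
plant_mirna_sites <- function(seqs, mirnas, n_per_class,
                              hosts = names(seqs), allowed_regions = NULL,
                              occupied = list()) {
  truth <- list()
  host_i <- 0L; mir_i <- 0L
  for (class in names(n_per_class)) {
    for (rep_ in seq_len(n_per_class[[class]])) {
      mir_i <- mir_i + 1L
      mid <- names(mirnas)[(mir_i - 1L) %% length(mirnas) + 1L]
      site <- make_site(mirnas[[mid]], class)
      width <- nchar(site$site)
      placed <- NULL
      for (h in seq_along(hosts)) {
        host_i <- host_i + 1L
        host <- hosts[(host_i - 1L) %% length(hosts) + 1L]
        region <- if (!is.null(allowed_regions) && host %in% names(allowed_regions)) {
          allowed_regions[[host]]
        } else c(0L, nchar(seqs[[host]]))
        placed <- allocate_window(occupied, host, width, region)
        if (!is.null(placed)) break
      }
      if (is.null(placed)) {
        stop("cannot place a ", class, " site without collision; ",
             "hosts are too small or too crowded")
      }
      occupied <- placed$occupied
      substr(seqs[[host]], placed$start + 1L, placed$end) <- site$site
      truth[[length(truth) + 1L]] <- data.frame(
        host_id = host, mirna_id = mid, rule_class = class,
        site_start = placed$start, site_end = placed$end,
        bulge_len = site$bulge_len, bulge_after = site$bulge_after,
        expected_expectation = site$expected_expectation,
        expected_mm_gu = site$expected_mm_gu,
        valid_target = site$expected_expectation <= 3,
        valid_etm = site$seed_perfect && site$expected_mm_gu <= 3 &&
          (site$bulge_len == 0L ||
             (site$bulge_len == 3L && site$bulge_after %in% 9:12)),
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
    else data.frame(host_id = character(), mirna_id = character(),
                    rule_class = character(), site_start = integer(),
                    site_end = integer(), bulge_len = integer(),
                    bulge_after = integer(), expected_expectation = numeric(),
                    expected_mm_gu = integer(), valid_target = logical(),
                    valid_etm = logical(), stringsAsFactors = FALSE)
  list(seqs = seqs, truth_sites = truth, occupied = occupied)
}

#' Plant hairpin copies (precursor positives and identity decoys)
#'
#' Positive copies carry 2 interior substitutions (identity >= 95 percent
#' for hairpins of >= 40 nt); decoys carry substitutions at every ninth
#' position (identity about 88.9 percent, below the strict 90 percent gate).
#'
#' @param seqs Named character vector of host sequences.
#' @param hairpins Named character vector of hairpin references.
#' @param n_pos,n_neg Planted positive / decoy copies.
#' @param hosts,allowed_regions,occupied As in [plant_mirna_sites].
#' @return list with `seqs`, `truth_precursors` and `occupied`.
#' @export
plant_precursors <- function(seqs, hairpins, n_pos, n_neg,
                             hosts = names(seqs), allowed_regions = NULL,
                             occupied = list()) {
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    v[pos] <- unname(c(A = "C", C = "G", G = "T", T = "A")[v[pos]])
    paste(v, collapse = "")
  }
  truth <- list()
  host_i <- 0L
  plan <- c(rep("pos", n_pos), rep("neg", n_neg))
  for (k in seq_along(plan)) {
    hid <- names(hairpins)[(k - 1L) %% length(hairpins) + 1L]
    hp <- hairpins[[hid]]
    h <- nchar(hp)
    if (plan[k] == "pos") {
      pos <- sort(rint(2L, 4L, h - 3L))
      copy <- mutate_at(hp, unique(pos))
      identity <- (h - length(unique(pos))) / h
    } else {
      nmut <- max(ceiling(h / 9), ceiling(h * 0.1) + 1L)
      pos <- unique(round(seq(4, h - 3, length.out = nmut)))
      copy <- mutate_at(hp, pos)
      identity <- (h - length(pos)) / h
    }
    placed <- NULL
    for (t in seq_along(hosts)) {
      host_i <- host_i + 1L
      host <- hosts[(host_i - 1L) %% length(hosts) + 1L]
      if (nchar(seqs[[host]]) < h + 10L) next
      region <- if (!is.null(allowed_regions) && host %in% names(allowed_regions)) {
        allowed_regions[[host]]
      } else c(0L, nchar(seqs[[host]]))
      placed <- allocate_window(occupied, host, h, region)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) stop("cannot place a hairpin copy without collision")
    occupied <- placed$occupied
    substr(seqs[[host]], placed$start + 1L, placed$end) <- copy
    truth[[length(truth) + 1L]] <- data.frame(
      host_id = host, hairpin_id = hid, class = plan[k],
      insert_start = placed$start, insert_end = placed$end,
      planted_identity = identity, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
    else data.frame(host_id = character(), hairpin_id = character(),
                    class = character(), insert_start = integer(),
                    insert_end = integer(), planted_identity = numeric(),
                    stringsAsFactors = FALSE)
  list(seqs = seqs, truth_precursors = truth, occupied = occupied)
}
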