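# Channel-of-interest assignment for the 128-channel HydroCel geodesic
# montage: five coarse scalp regions; channels not listed are "marginal".
.regionChannels <- list(
  F = c("E2", "E3", "E4", "E5", "E9", "E10", "E11", "E12", "E15", "E16",
        "E18", "E19", "E22", "E23", "E24", "E26", "E27", "E123", "E124"),
  LT = c("E28", "E33", "E34", "E35", "E39", "E40", "E41", "E45", "E46",
         "E47", "E50", "E51", "E52", "E58"),
  C = c("E6", "E7", "E13", "E20", "E29", "E30", "E31", "E36", "E37", "E42",
        "E53", "E54", "E55", "E79", "E80", "E86", "E87", "E93", "E104",
        "E105", "E106", "E111", "E112", "E118"),
  RT = c("E92", "E96", "E97", "E98", "E101", "E102", "E103", "E108",
         "E109", "E110", "E115", "E116", "E117", "E122"),
  P = c("E59", "E60", "E61", "E62", "E65", "E66", "E67", "E70", "E71",
        "E72", "E75", "E76", "E77", "E78", "E83", "E84", "E85", "E90",
        "E91"))

#' Scalp region map for the 128-channel geodesic montage
#'
#' Maps channel labels to the five scalp regions used for reporting:
#' frontal (F), left temporal (LT), central (C), right temporal (RT) and
#' posterior (P). Channels outside the channels-of-interest list are labeled
#' \code{"marginal"}.
#'
#' @param channels channel labels to map; defaults to E1..E128.
#' @return named character vector channel -> region.
#' @examples
#' regionMap(c("E33", "E104"))  # LT, C
#' @export
regionMap <- function(channels = paste0("E", 1:128)) {
  map <- rep("marginal", length(channels))
  names(map) <- channels
  for (region in names(.regionChannels)) {
    hit <- channels %in% .regionChannels[[region]]
    map[hit] <- region
  }
  map
}

#' Selection-frequency report
#'
#' Ranks features by how often the t-test + LASSO pipeline selected them
#' across all outer folds and repeats of a nested CV run (ties broken by
#' lower feature index) and annotates them anatomically: each low-order
#' feature with its channel pair and the pair's regions; each high-order
#' feature with its cluster pair and the region sets spanned by the member
#' pairs of the two clusters. High-order counts are tracked per cluster
#' count k, and the report uses the k most often chosen across folds
#' (lowest k on ties), with cluster composition taken from the all-subject
#' reference clustering stored in the report.
#'
#' @param report a \code{"bfnCVReport"} from \code{nestedCV}.
#' @param network which network to report on; default the first.
#' @param topN how many features to list per order; capped at the number of
#'   features with nonzero rank information.
#' @param regions named channel -> region map, as from \code{regionMap}.
#' @return list with data.frames \code{lowOrder} and \code{highOrder}.
#' @export
selectionFrequencyReport <- function(report, network = report$networks[1L],
                                     topN = 10,
                                     regions = regionMap()) {
  stopifnot(inherits(report, "bfnCVReport"), network %in% report$networks)
  rankTop <- function(counts, n) {
    ord <- order(-counts, seq_along(counts))
    ord[seq_len(min(n, length(counts)))]
  }
  loCounts <- report$selection$lo[[network]]
  # channel metadata if the series carry it
  loIdx <- rankTop(loCounts, topN)
  lo <- data.frame(feature = loIdx, count = loCounts[loIdx])
  lo$label <- paste0("pair", loIdx)
  chl <- report$channelLabels[[network]] %||% NULL
  prm <- report$pairs[[network]] %||% NULL
  if (!is.null(prm) && nrow(prm) > 0L) {
    i <- prm[loIdx, 1L]; j <- prm[loIdx, 2L]
    if (!is.null(chl) && length(chl) > 0L) {
      lo$channel_i <- chl[i]
      lo$channel_j <- chl[j]
      lo$region_i <- unname(regions[match(lo$channel_i, names(regions))])
      lo$region_j <- unname(regions[match(lo$channel_j, names(regions))])
      lo$label <- paste0(lo$channel_i, "-", lo$channel_j)
    } else {
      lo$channel_i <- i; lo$channel_j <- j
      lo$label <- paste0("ch", i, "-ch", j)
    }
  }
  # modal k: the k chosen most often across folds
  ks <- vapply(report$folds, `[[`, 0, "k")
  tab <- table(ks)
  kModal <- as.numeric(names(tab)[which.max(tab)])
  hoCounts <- report$selection$ho[[network]][[as.character(kModal)]]
  assign <- report$referenceAssignments[[network]][[as.character(kModal)]]
  kp <- pairIndex(assign@k)
  hoIdx <- rankTop(hoCounts, topN)
  regionSet <- function(cluster) {
    if (is.null(prm) || nrow(prm) == 0L || is.null(chl) ||
        length(chl) == 0L)
      return(NA_character_)
    mem <- which(assign@labels == cluster)
    chs <- unique(chl[unique(as.vector(prm[mem, , drop = FALSE]))])
    paste(sort(unique(unname(regions[match(chs, names(regions))]))),
          collapse = ",")
  }
  ho <- data.frame(feature = hoIdx, count = hoCounts[hoIdx],
                   cluster1 = kp[hoIdx, 1L], cluster2 = kp[hoIdx, 2L],
                   k = kModal)
  ho$regions1 <- vapply(ho$cluster1, regionSet, "")
  ho$regions2 <- vapply(ho$cluster2, regionSet, "")
  list(lowOrder = lo, highOrder = ho)
}
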