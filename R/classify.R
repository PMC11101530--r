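#' Classification thresholds for morphological groups
#'
#' Area-based decision rule separating the morphological groups observed
#' in microparticle-enhanced *Streptomyces* cultivations: free spores
#' (only present at inoculation, 0 h), small clumps and free hyphae
#' (projected areas up to ~164 um^2), and large pellets (10^4-10^6
#' um^2). The observed group ranges leave a wide gap; the pellet/clump
#' boundary `pellet_min_um2` is placed in it. Objects below
#' `debris_floor_um2` are debris.
#'
#' @param debris_floor_um2 Objects with `A` below this are debris
#'   (default 20 um^2).
#' @param spore_cap_um2 At 0 h, objects with `A` at or below this are
#'   spores (default 300 um^2).
#' @param pellet_min_um2 Objects with `A` above this are pellets, at or
#'   below it clumps/hyphae (default 1000 um^2; boundary inclusive on
#'   the clump side).
#' @return A list of class `morpho_thresholds`.
#' @export
morpho_thresholds <- function(debris_floor_um2 = 20,
                              spore_cap_um2 = 300,
                              pellet_min_um2 = 1000) {
  stop_if_not_scalar_num(debris_floor_um2, "debris_floor_um2", 0)
  stop_if_not_scalar_num(spore_cap_um2, "spore_cap_um2", 0)
  stop_if_not_scalar_num(pellet_min_um2, "pellet_min_um2", 0)
  structure(
    list(
      debris_floor_um2 = debris_floor_um2,
      spore_cap_um2 = spore_cap_um2,
      pellet_min_um2 = pellet_min_um2
    ),
    class = "morpho_thresholds"
  )
}

#' Classify objects into morphological groups
#'
#' Applies the area decision rule of [morpho_thresholds()] to each
#' object: debris below the floor; spores at 0 h below the spore cap;
#' otherwise clump/hyphae up to `pellet_min_um2` and pellet above it.
#' Every object receives a class.
#'
#' @param a_um2 Projected area(s), um^2.
#' @param time_h Sampling time(s), h (vectorised with `a_um2`).
#' @param thresholds A [morpho_thresholds()].
#' @return Character vector of class labels in
#'   `c("debris", "spore", "clump_hyphae", "pellet")`.
#' @examples
#' classify_area(c(164, 1e5, 50), time_h = c(24, 96, 0))
#' @export
classify_area <- function(a_um2, time_h, thresholds = morpho_thresholds()) {
  stopifnot(inherits(thresholds, "morpho_thresholds"))
  n <- max(length(a_um2), length(time_h))
  a_um2 <- rep_len(a_um2, n)
  time_h <- rep_len(time_h, n)
  out <- ifelse(a_um2 <= thresholds$pellet_min_um2, "clump_hyphae", "pellet")
  out[time_h == 0 & a_um2 <= thresholds$spore_cap_um2] <- "spore"
  out[a_um2 < thresholds$debris_floor_um2] <- "debris"
  out
}

#' Classify a table of measured objects
#'
#' Adds a `class` column to the output of [measure_objects()].
#'
#' @param records Data.frame with columns `A_um2` and `time_h`.
#' @param thresholds A [morpho_thresholds()].
#' @return `records` with a `class` column appended.
#' @export
classify_objects <- function(records, thresholds = morpho_thresholds()) {
  stopifnot(is.data.frame(records), all(c("A_um2", "time_h") %in% names(records)))
  records$class <- classify_area(records$A_um2, records$time_h, thresholds)
  records
}

#' Summarise morphological groups
#'
#' Per (class, time, condition) group, reports for each descriptor (`A`,
#' `E`, `S`, `D`, `Mo`) the number of objects, mean, standard deviation
#' (n-1 denominator) and Student-t confidence band at level `1 - alpha`,
#' plus a `sufficient_n` flag that is `TRUE` when the group holds at
#' least 30 objects (the usual floor for reporting mean morphological
#' parameters). Groups of one object get `NA` SD and band.
#'
#' @param records Classified object table ([classify_objects()]).
#' @param alpha Significance level of the band (default 0.05).
#' @return A data.frame with one row per group x descriptor:
#'   `class`, `time_h`, `talc_g_per_L`, `param`, `n`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`, `sufficient_n`.
#' @export
summarize_morphology <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records), "class" %in% names(records))
  params <- c(A = "A_um2", E = "E", S = "S", D = "D_um", Mo = "Mo")
  key <- interaction(records$class, records$time_h, records$talc_g_per_L,
    drop = TRUE
  )
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    do.call(rbind, lapply(names(params), function(p) {
      v <- g[[params[[p]]]]
      v <- v[is.finite(v)]
      if (length(v) == 0L) {
        return(NULL)
      }
      s <- mean_sd_ci(v, alpha)
      data.frame(
        class = g$class[1], time_h = g$time_h[1],
        talc_g_per_L = g$talc_g_per_L[1], param = p,
        n = s$n, mean = s$mean, sd = s$sd,
        ci_lo = s$ci_lo, ci_hi = s$ci_hi,
        sufficient_n = s$n >= 30L
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$class, out$time_h, out$talc_g_per_L, out$param), ]
}
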