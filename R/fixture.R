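#' Synthetic two-year quality-report registries mirroring the published cohort
#'
#' Constructs, fully deterministically and in code, a pair of hospital-site
#' registries (plus the matching area-attribute table) whose cohort
#' arithmetic reproduces the published study exactly: 747 baseline obstetric
#' sites of which 85 close by follow-up (662 remain), 13 of the closures
#' being whole-hospital closures and 32 baseline sites university hospitals
#' (none of which closes), leaving 702 sites with 72 closure events in the
#' regression sample; pediatrics on site at 308 baseline (41.23%) and 304
#' follow-up (45.92%) obstetric sites; median annual live births 702 at
#' baseline and 879 at follow-up (+25.21%), 683 within the regression
#' sample; and, in the 900--1,200 births band, exactly 1 of the 308
#' pediatrics-equipped sites (0.32%) and 2 of the 439 sites without
#' pediatrics (0.46%) closing. Ownership, teaching, density and fertility
#' marginals match the published regression-sample table. A handful of
#' non-obstetric, zero-birth and day-care distractor records exercise the
#' site-identification rules.
#'
#' This is synthetic data: site identities, locations and attribute joints
#' are constructed, only the printed margins are matched.
#'
#' @return list with `baseline` (registry data.frame, reporting year 2014),
#'   `followup` (2019) and `areas` (area-attribute table).
#' @export
synthetic_quality_reports <- function() {
  interp <- function(rank_anchor, val_anchor, n) {
    round(stats::approx(rank_anchor, val_anchor, xout = seq_len(n))$y)
  }
  # deterministic interleaving permutations (no RNG)
  perm_of <- function(n, phase) order(sin(seq_len(n) + phase))
  fill_counts <- function(n, counts, phase) {
    v <- rep(names(counts), counts)
    out <- character(n)
    out[perm_of(n, phase)] <- v
    out
  }

  ## --- the 702-site regression sample ------------------------------------
  n_s <- 702L
  births <- interp(c(1, 176, 351, 352, 361, 527, 702),
                   c(15, 450, 683, 683, 702, 1126, 5081), n_s)
  ped_ranks <- c(seq(2L, 347L, by = 5L), 496:702)      # 70 + 207 = 277
  ped <- seq_len(n_s) %in% ped_ranks
  nonped_ranks <- setdiff(seq_len(n_s), ped_ranks)
  closure_ranks <- c(utils::head(nonped_ranks, 66), 450L, 470L,  # 68 without ped.
                     2L, 7L, 12L, 500L)                          # 4 with ped.
  closed <- seq_len(n_s) %in% closure_ranks

  ownership <- fill_counts(n_s, c(nonprofit = 280, public = 303, private = 119), 0.0)
  teaching <- fill_counts(n_s, c(no = 236, yes = 466), 0.3)
  dens <- fill_counts(n_s, c(low = 35, medium = 292, high = 375), 0.6)
  fert <- fill_counts(n_s, c(low = 35, medium = 527, high = 140), 0.9)

  sample_df <- data.frame(
    births2014 = births, ped = ped, closed = closed, whole = FALSE,
    ownership = ownership, teaching = teaching, dens = dens, fert = fert,
    stringsAsFactors = FALSE
  )

  ## --- excluded strata: 32 university, 13 whole-hospital closures ---------
  uni <- data.frame(
    births2014 = round(seq(2000, 5000, length.out = 32)),
    ped = c(rep(TRUE, 31), FALSE), closed = FALSE, whole = FALSE,
    ownership = c(rep("nonprofit", 5), rep("public", 26), "private"),
    teaching = "university",
    dens = "high", fert = "medium",
    stringsAsFactors = FALSE
  )
  whole <- data.frame(
    births2014 = round(seq(100, 400, length.out = 13)),
    ped = FALSE, closed = TRUE, whole = TRUE,
    ownership = c(rep("nonprofit", 4), rep("public", 7), rep("private", 2)),
    teaching = c(rep("no", 9), rep("yes", 4)),
    dens = c(rep("medium", 6), rep("high", 7)),
    fert = "medium",
    stringsAsFactors = FALSE
  )
  all_sites <- rbind(sample_df, uni, whole)
  n <- nrow(all_sites)  # 747
  all_sites$site_id <- sprintf("H%04d", seq_len(n))

  ## --- area table: one cell per (density, fertility) combination ----------
  dens_raw <- c(low = 80, medium = 500, high = 1500)
  fert_raw <- c(low = 1.2, medium = 1.45, high = 1.7)
  combos <- expand.grid(dens = names(dens_raw), fert = names(fert_raw),
                        stringsAsFactors = FALSE)
  areas <- data.frame(
    postal_area = sprintf("A%s%s", toupper(substr(combos$dens, 1, 1)),
                          toupper(substr(combos$fert, 1, 1))),
    density_raw = dens_raw[combos$dens],
    density_category = combos$dens,
    fertility_rate = fert_raw[combos$fert],
    stringsAsFactors = FALSE
  )
  rownames(areas) <- NULL
  all_sites$postal_area <- sprintf("A%s%s",
                                   toupper(substr(all_sites$dens, 1, 1)),
                                   toupper(substr(all_sites$fert, 1, 1)))

  ## --- registries ---------------------------------------------------------
  grid_xy <- function(i) list(x = (i %% 30L) * 20 + 5, y = (i %/% 30L) * 20 + 5)
  xy <- grid_xy(seq_len(n) - 1L)
  baseline <- data.frame(
    site_id = all_sites$site_id,
    year = 2014L,
    node_id = "",
    x = xy$x, y = xy$y,
    postal_area = all_sites$postal_area,
    facility_type = "acute",
    departments = ifelse(all_sites$ped, "2500;2400;1000", "2500;2400"),
    procedures = births_to_procedures(all_sites$births2014),
    ownership = all_sites$ownership,
    teaching = all_sites$teaching,
    whole_hospital_closed = FALSE,
    stringsAsFactors = FALSE
  )

  surv <- !all_sites$closed
  surv_df <- all_sites[surv, , drop = FALSE]
  o <- order(surv_df$births2014)
  births2019 <- integer(nrow(surv_df))
  births2019[o] <- interp(c(1, 166, 331, 332, 497, 662),
                          c(32, 577, 879, 879, 1511, 5670), nrow(surv_df))
  fu_surv <- baseline[surv, , drop = FALSE]
  fu_surv$year <- 2019L
  fu_surv$procedures <- births_to_procedures(births2019)

  dept_cl <- all_sites$closed & !all_sites$whole
  fu_dept <- baseline[dept_cl, , drop = FALSE]
  fu_dept$year <- 2019L
  fu_dept$departments <- ifelse(all_sites$ped[dept_cl], "1000", "0100")
  fu_dept$procedures <- ""

  whole_idx <- which(all_sites$whole)
  flagged_idx <- whole_idx[seq_len(8)]       # present, flagged closed
  # the remaining 5 whole closures vanish from the follow-up registry entirely
  fu_whole <- baseline[flagged_idx, , drop = FALSE]
  fu_whole$year <- 2019L
  fu_whole$departments <- ""
  fu_whole$procedures <- ""
  fu_whole$whole_hospital_closed <- TRUE

  distract <- function(year) data.frame(
    site_id = sprintf("X%03d", 1:20),
    year = year, node_id = "", x = 1, y = 1,
    postal_area = "AHM", facility_type = c(rep("acute", 16), rep("day_care", 4)),
    departments = c(rep("2900", 12), rep("2500;2400", 8)),
    procedures = c(rep("", 12), rep("9-262.0:0", 4), rep("9-262.0:120;9-262.1:40", 4)),
    ownership = "public", teaching = "no", whole_hospital_closed = FALSE,
    stringsAsFactors = FALSE
  )
  baseline <- rbind(baseline, distract(2014L))
  followup <- rbind(fu_surv, fu_dept, fu_whole, distract(2019L))
  rownames(baseline) <- rownames(followup) <- NULL

  ## --- self-checks against the published margins --------------------------
  stopifnot(
    nrow(sample_df) == 702L, sum(sample_df$closed) == 72L,
    sum(all_sites$closed) == 85L, sum(all_sites$whole) == 13L,
    sum(all_sites$teaching == "university") == 32L,
    sum(all_sites$ped) == 308L,
    sum(all_sites$ped[!all_sites$closed]) + 0L == 304L,
    stats::median(all_sites$births2014) == 702,
    stats::median(sample_df$births2014) == 683,
    stats::median(births2019) == 879,
    sum(all_sites$ped & all_sites$closed &
          all_sites$births2014 >= 900 & all_sites$births2014 <= 1200) == 1L,
    sum(!all_sites$ped & all_sites$closed &
          all_sites$births2014 >= 900 & all_sites$births2014 <= 1200) == 2L
  )
  list(baseline = baseline, followup = followup, areas = areas)
}
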