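#' Derive the clinical covariate profile of a cohort
#'
#' Builds the adjustment covariates from raw measurements, recorded
#' diagnoses and dispensed treatments, following the usual primary-care
#' operational definitions:
#' \itemize{
#' \item hypertension: at least two blood-pressure readings with
#'   SBP >= 140 and/or DBP >= 90 mmHg, a recorded diagnosis, or
#'   antihypertensive treatment;
#' \item high-normal blood pressure: at least two readings with SBP
#'   130--139 and/or DBP 85--89 mmHg, or diagnosed hypertension;
#' \item type-2 diabetes: one random glucose >= 200 mg/dL, two fasting
#'   glucose >= 126 mg/dL, two HbA1c >= 6.5\%, two 2-hour glucose
#'   >= 200 mg/dL, a recorded diagnosis, or antidiabetic treatment;
#' \item impaired fasting glucose: basal (fasting) glucose >= 110 mg/dL;
#' \item obesity: body-mass index > 30 kg/m2;
#' \item low HDL: < 40 mg/dL in men, < 50 mg/dL in women;
#' \item hypertriglyceridemia: triglycerides >= 150 mg/dL;
#' \item metabolic syndrome: three or more of \{diabetes or impaired
#'   fasting glucose, hypertension or high-normal BP, low HDL,
#'   hypertriglyceridemia, obesity\}.
#' }
#'
#' Flags are three-valued: `TRUE` when the rule is met, `FALSE` when
#' relevant data are present but the rule is not met, `NA` when no
#' relevant input exists for the participant — a missing input is never
#' silently coded as absent disease.
#'
#' @param participants data frame with `pid`, `sex` (see
#'   [ckd_epi_egfr()] for accepted codings) and optionally `smoking`
#'   (0 non-smoker / 1 smoker / 2 former), `alcohol` (0 none /
#'   1 drinker / 2 former) and `country_spain` (0/1).
#' @param measurements per-visit measurement table: `pid`, `day`, and
#'   any of `sbp`, `dbp`, `fasting_glucose`, `random_glucose`,
#'   `glucose_2h`, `hba1c`, `bmi`, `hdl`, `tg` (NA when not measured).
#'   May be `NULL`.
#' @param diagnoses long table `pid`, `condition`, `onset_day`;
#'   conditions `"hypertension"` and `"diabetes"` feed the flags, any
#'   others count towards `chronic_count`.  May be `NULL`.
#' @param treatments long table `pid`, `treatment`, `start_day` with
#'   treatments among `"antihypertensive"`, `"antidiabetic"`,
#'   `"lipid_lowering"`, `"nsaid"`.  May be `NULL`.
#' @return data frame, one row per participant, with logical flags
#'   (`hypertension`, `high_normal_bp`, `diabetes`,
#'   `impaired_fasting_glucose`, `obesity`, `low_hdl`,
#'   `hypertriglyceridemia`, `metabolic_syndrome`), integer
#'   `chronic_count`, lifestyle columns, and 0/1 treatment flags.
#' @export
derive_covariates <- function(participants, measurements = NULL,
                              diagnoses = NULL, treatments = NULL) {
  pids <- participants$pid
  female <- parse_sex(participants$sex)
  n <- length(pids)

  m_of <- function(col) {
    if (is.null(measurements) || is.null(measurements[[col]])) return(NULL)
    measurements[!is.na(measurements[[col]]), c("pid", "day", col)]
  }
  count_by <- function(df, cond) {
    out <- integer(n)
    if (is.null(df) || nrow(df) == 0L) return(out)
    hit <- df[cond(df), "pid"]
    tab <- table(factor(hit, levels = pids))
    as.integer(tab)
  }
  seen <- function(df) count_by(df, function(d) rep(TRUE, nrow(d))) > 0L

  has_dx <- function(cond) {
    if (is.null(diagnoses)) return(rep(NA, n))
    pids %in% diagnoses$pid[diagnoses$condition == cond]
  }
  has_tx <- function(tx) {
    if (is.null(treatments)) return(rep(NA, n))
    pids %in% treatments$pid[treatments$treatment == tx]
  }

  # three-valued OR over evidence sources: TRUE wins, else FALSE if any
  # source was observed, else NA
  tri_or <- function(...) {
    src <- list(...)
    out <- rep(NA, n)
    for (s in src) out <- ifelse(!is.na(s) & s, TRUE, out)
    observed <- Reduce(`|`, lapply(src, function(s) !is.na(s)))
    ifelse(is.na(out) & observed, FALSE, out)
  }

  bp <- NULL
  if (!is.null(measurements) &&
      (!is.null(measurements$sbp) || !is.null(measurements$dbp))) {
    bp <- measurements[, c("pid", "day"), drop = FALSE]
    bp$sbp <- measurements$sbp %||% rep(NA_real_, nrow(bp))
    bp$dbp <- measurements$dbp %||% rep(NA_real_, nrow(bp))
    bp <- bp[!is.na(bp$sbp) | !is.na(bp$dbp), , drop = FALSE]
    if (nrow(bp) == 0L) bp <- NULL
  }
  n_ht_read <- count_by(bp, function(d)
    (!is.na(d$sbp) & d$sbp >= 140) | (!is.na(d$dbp) & d$dbp >= 90))
  n_hn_read <- count_by(bp, function(d)
    (!is.na(d$sbp) & d$sbp >= 130 & d$sbp <= 139) |
      (!is.na(d$dbp) & d$dbp >= 85 & d$dbp <= 89))
  bp_measured <- if (is.null(bp)) rep(NA, n) else
    ifelse(seen(bp), FALSE, NA)  # observed-baseline for tri_or

  hypertension <- tri_or(
    ifelse(is.na(bp_measured), NA, n_ht_read >= 2),
    has_dx("hypertension"), has_tx("antihypertensive"))
  high_normal_bp <- tri_or(
    ifelse(is.na(bp_measured), NA, n_hn_read >= 2),
    has_dx("hypertension"))

  fg <- m_of("fasting_glucose")
  rg <- m_of("random_glucose")
  g2 <- m_of("glucose_2h")
  a1c <- m_of("hba1c")
  diabetes <- tri_or(
    if (is.null(rg)) rep(NA, n) else
      ifelse(seen(rg), count_by(rg, function(d) d$random_glucose >= 200) >= 1, NA),
    if (is.null(fg)) rep(NA, n) else
      ifelse(seen(fg), count_by(fg, function(d) d$fasting_glucose >= 126) >= 2, NA),
    if (is.null(a1c)) rep(NA, n) else
      ifelse(seen(a1c), count_by(a1c, function(d) d$hba1c >= 6.5) >= 2, NA),
    if (is.null(g2)) rep(NA, n) else
      ifelse(seen(g2), count_by(g2, function(d) d$glucose_2h >= 200) >= 2, NA),
    has_dx("diabetes"), has_tx("antidiabetic"))
  impaired_fasting_glucose <- if (is.null(fg)) rep(NA, n) else
    ifelse(seen(fg), count_by(fg, function(d) d$fasting_glucose >= 110) >= 1, NA)

  bmi <- m_of("bmi")
  obesity <- if (is.null(bmi)) rep(NA, n) else
    ifelse(seen(bmi), count_by(bmi, function(d) d$bmi > 30) >= 1, NA)
  hdl <- m_of("hdl")
  low_hdl <- if (is.null(hdl)) rep(NA, n) else {
    thr <- ifelse(female, 50, 40)
    low <- vapply(seq_len(n), function(i) {
      v <- hdl$hdl[hdl$pid == pids[i]]
      if (!length(v)) NA else any(v < thr[i])
    }, logical(1))
    low
  }
  tg <- m_of("tg")
  hypertriglyceridemia <- if (is.null(tg)) rep(NA, n) else
    ifelse(seen(tg), count_by(tg, function(d) d$tg >= 150) >= 1, NA)

  # metabolic syndrome: >=3 of the 5 components; NA only when the
  # undetermined components could still tip the count over 3
  comp <- cbind(
    tri_or(diabetes, impaired_fasting_glucose),
    tri_or(hypertension, high_normal_bp),
    low_hdl, hypertriglyceridemia, obesity)
  n_true <- rowSums(comp, na.rm = TRUE)
  n_na <- rowSums(is.na(comp))
  metabolic_syndrome <- ifelse(n_true >= 3, TRUE,
    ifelse(n_true + n_na < 3, FALSE, NA))

  chronic_conditions <- c("ischemic_heart_disease", "heart_failure",
    "atrial_fibrillation", "peripheral_arteriopathy", "lv_hypertrophy",
    "stroke", "dementia", "retinopathy", "macular_edema", "cancer",
    "cardiovascular_disease")
  chronic_count <- if (is.null(diagnoses)) rep(NA_integer_, n) else
    vapply(pids, function(p) sum(diagnoses$pid == p &
      diagnoses$condition %in% chronic_conditions), integer(1))

  tx01 <- function(tx) {
    v <- has_tx(tx)
    ifelse(is.na(v), NA_integer_, as.integer(v))
  }
  data.frame(pid = pids,
             female = as.integer(female),
             country_spain = participants$country_spain %||% rep(NA_integer_, n),
             hypertension = hypertension,
             high_normal_bp = high_normal_bp,
             diabetes = diabetes,
             impaired_fasting_glucose = impaired_fasting_glucose,
             obesity = obesity,
             low_hdl = low_hdl,
             hypertriglyceridemia = hypertriglyceridemia,
             metabolic_syndrome = metabolic_syndrome,
             chronic_count = chronic_count,
             smoking = participants$smoking %||% rep(NA_integer_, n),
             alcohol = participants$alcohol %||% rep(NA_integer_, n),
             antihypertensive = tx01("antihypertensive"),
             antidiabetic = tx01("antidiabetic"),
             lipid_lowering = tx01("lipid_lowering"),
             nsaid = tx01("nsaid"))
}
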