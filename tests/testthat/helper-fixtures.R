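# Shared fixtures and independent oracles, built in code at test time.

unit_square_ring <- function(side = 1, x0 = 0, y0 = 0) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# Slide with one square region of side_px pixels and given marks.
square_slide <- function(side_px = 1000, mpp = 1, marks = list(),
                         holes = list(), id = "s1") {
  calibrated_slide(id, mpp,
                   list(tissue_region(unit_square_ring(side_px), holes = holes)),
                   marks)
}

# Independent winding-number point-in-polygon oracle (non-zero rule; for
# simple polygons without holes it coincides with even-odd away from the
# boundary).
winding_inside <- function(p, ring) {
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ]
    b <- ring[if (i == n) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])
    if (a[2] <= p[2]) {
      if (b[2] > p[2] && cr > 0) wn <- wn + 1
    } else {
      if (b[2] <= p[2] && cr < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Random star-shaped (hence simple) polygon around a centre.
random_simple_polygon <- function(n_vertices = 8, radius = 10) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.3 * radius, radius)
  cbind(r * cos(ang), r * sin(ang))
}

# Brute-force AUC: concordant event/non-event pairs, half credit for ties.
brute_force_auc <- function(values, events) {
  ev <- values[events]
  nev <- values[!events]
  total <- 0
  for (a in ev) for (b in nev) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(ev) * length(nev))
}

# Cohort reconstructed from the published per-diagnosis counts: 52 IPF
# (12 with no foci, 19 p16-low positives, 21 p16-high), 34 non-IPF of which
# exactly 3 show foci (densities 3.82, 1.08, 1.32), and 31/13/42
# alive/transplanted/died overall.
make_printed_counts_cohort <- function() {
  density <- c(rep(0, 12), rep(1.0, 19), rep(3.0, 21),     # IPF
               rep(0, 16),                                  # NSIP
               3.82, 1.08, rep(0, 9),                       # unclassifiable
               1.32, rep(0, 5),                             # chronic HP
               0)                                           # smoking-related
  diagnosis <- c(rep("IPF", 52), rep("NSIP", 16), rep("unclassifiable", 11),
                 rep("chronic_HP", 6), "smoking_related")
  # interleave outcomes across the diagnosis blocks (fixed permutation) so
  # the fixture keeps the printed 31/13/42 split without degenerate structure
  scrambled <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(2026)
    s <- list(status = sample(c(rep("alive", 31), rep("transplanted", 13),
                                rep("died", 42))),
              followup = sample(seq(0.5, 86, length.out = 86)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    s
  })
  status <- scrambled$status
  data.frame(patient_id = sprintf("P%02d", 1:86),
             diagnosis = diagnosis,
             density = density,
             age = 62, sex = rep(c("M", "F"), length.out = 86), bmi = 30,
             treatment = rep(c("antifibrotic", "immunomodulatory", "none"),
                             length.out = 86),
             followup_months = scrambled$followup,
             status = status,
             post_biopsy_lung_cancer = 0L,
             stringsAsFactors = FALSE)
}

# Tiny survival fixture with events only early in group A:
# A: events at 1 and 2; B: censored at 3 and 4.
two_group_records <- function() {
  list(a = data.frame(time = c(1, 2), event = c(TRUE, TRUE)),
       b = data.frame(time = c(3, 4), event = c(FALSE, FALSE)))
}

random_survival_data <- function(n, beta = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(beta * x))
  cens <- rexp(n, 0.03)
  data.frame(time = pmin(t, cens), event = t <= cens, x = x)
}
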