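test_that("metric kernel matches hand arithmetic", {
    # pseudo-patient built from the reference right/left TS means
    expect_equal(asymmetryValue(128.1691, 126.3527, "delta"), 1.8164,
                 tolerance = 1e-10)
    expect_equal(asymmetryValue(150, 50, "Delta"), 0.5)
    expect_equal(asymmetryValue(150, 50, "sqrt_abs_Delta"), sqrt(0.5))
    expect_equal(asymmetryValue(50, 150, "abs_Delta"), 0.5)
    expect_equal(asymmetryValue(120, 80, "Delta_bar", refSum = 250), 40 / 250)
    expect_equal(asymmetryValue(120, 80, "Delta_dbar", globalSum = 160), 0.25)
    # perfect symmetry gives zero under every metric
    for (m in asymmetryMetrics()) {
        z <- if (m %in% c("Delta_bar", "abs_Delta_bar"))
            asymmetryValue(100, 100, m, refSum = 200)
        else asymmetryValue(100, 100, m, globalSum = 200)
        expect_equal(z, 0, info = m)
    }
    expect_error(asymmetryValue(0, 100, "delta"), "> 0")
    expect_error(asymmetryValue(120, 80, "Delta_bar"), "refSum")
})

test_that("exactly nine metric identifiers exist", {
    expect_length(asymmetryMetrics(), 9)
    expect_setequal(asymmetryMetrics(),
        c("delta", "abs_delta", "Delta", "abs_Delta", "Delta_bar",
          "abs_Delta_bar", "Delta_dbar", "abs_Delta_dbar", "sqrt_abs_Delta"))
})

test_that("cohort sector means are per-eye arithmetic means", {
    co <- makeCohort(
        right = list(flat6(100), flat6(110)),
        left = list(flat6(90), flat6(130)),
        label = c("healthy", "glaucoma"))
    m <- cohortSectorMeans(co)
    expect_equal(unname(m["right", "TS"]), 105)
    expect_equal(unname(m["left", "N"]), 110)
    expect_equal(attr(m, "n"), 2)
    co1 <- makeCohort(list(flat6(100)), list(flat6(90)), "healthy")
    expect_equal(unname(cohortSectorMeans(co1)["right", SECTORS6]), rep(100, 6))
})

test_that("feature matrices follow the formulas on a hand-checked cohort", {
    co <- toyCohort()  # P1 symmetric 100/100, P2 right 120 / left 80
    fm <- function(m) featureMatrix(asymmetryFeatures(co, m))
    expect_equal(unname(fm("delta")[1, ]), rep(0, 7))
    expect_equal(unname(fm("delta")[2, ]), rep(40, 7))
    expect_equal(unname(fm("Delta")[2, ]), rep(0.2, 7))
    expect_equal(unname(fm("abs_Delta")[2, ]), rep(0.2, 7))
    expect_equal(unname(fm("sqrt_abs_Delta")[2, ]), rep(sqrt(0.2), 7))
    # Delta_bar uses pooled cohort means: (110 + 90) per sector
    expect_equal(unname(fm("Delta_bar")[2, "TS"]), 40 / 200)
    # Delta_dbar divides by the patient's own global sum
    expect_equal(unname(fm("Delta_dbar")[2, "TI"]), 40 / 200)
    expect_identical(colnames(fm("delta")), c("TS", "T", "TI", "NS", "N", "NI", "G"))
})

test_that("signed metrics are antisymmetric and absolute metrics even under eye swap", {
    co <- generateCohort(seed = 3)
    swapped <- RNFLCohort(right = leftEye(co)[SECTORS6, ],
                          left = rightEye(co)[SECTORS6, ],
                          label = as.character(diagnosis(co)),
                          patientId = colnames(co))
    for (m in c("delta", "Delta", "Delta_bar", "Delta_dbar"))
        expect_equal(featureMatrix(asymmetryFeatures(swapped, m)),
                     -featureMatrix(asymmetryFeatures(co, m)),
                     tolerance = 1e-12, info = m)
    for (m in c("abs_delta", "abs_Delta", "abs_Delta_bar", "abs_Delta_dbar",
                "sqrt_abs_Delta"))
        expect_equal(featureMatrix(asymmetryFeatures(swapped, m)),
                     featureMatrix(asymmetryFeatures(co, m)),
                     tolerance = 1e-12, info = m)
})

test_that("absolute metrics equal the absolute value of their signed partners", {
    co <- generateCohort(seed = 4)
    pairs <- list(c("delta", "abs_delta"), c("Delta", "abs_Delta"),
                  c("Delta_bar", "abs_Delta_bar"), c("Delta_dbar", "abs_Delta_dbar"))
    for (p in pairs)
        expect_equal(featureMatrix(asymmetryFeatures(co, p[2])),
                     abs(featureMatrix(asymmetryFeatures(co, p[1]))),
                     tolerance = 1e-12, info = p[2])
    expect_equal(featureMatrix(asymmetryFeatures(co, "sqrt_abs_Delta")),
                 sqrt(featureMatrix(asymmetryFeatures(co, "abs_Delta"))),
                 tolerance = 1e-12)
})

test_that("per-patient normalizations are scale invariant; delta scales linearly", {
    co <- generateCohort(seed = 5)
    scaled <- RNFLCohort(right = 3 * rightEye(co)[SECTORS6, ],
                         left = 3 * leftEye(co)[SECTORS6, ],
                         label = as.character(diagnosis(co)),
                         patientId = colnames(co))
    for (m in c("Delta", "Delta_dbar", "Delta_bar"))
        expect_equal(featureMatrix(asymmetryFeatures(scaled, m)),
                     featureMatrix(asymmetryFeatures(co, m)),
                     tolerance = 1e-12, info = m)
    expect_equal(featureMatrix(asymmetryFeatures(scaled, "delta")),
                 3 * featureMatrix(asymmetryFeatures(co, "delta")),
                 tolerance = 1e-10)
})

test_that("Delta and Delta_dbar coincide on the G feature", {
    co <- generateCohort(seed = 6)
    expect_equal(featureMatrix(asymmetryFeatures(co, "Delta"))[, "G"],
                 featureMatrix(asymmetryFeatures(co, "Delta_dbar"))[, "G"],
                 tolerance = 1e-14)
})

test_that("normalized metrics respect their ranges on generated cohorts", {
    co <- generateCohort(seed = 7)
    for (m in c("Delta", "Delta_bar", "Delta_dbar")) {
        v <- featureMatrix(asymmetryFeatures(co, m))
        expect_true(all(v >= -1 & v <= 1), info = m)
    }
    for (m in c("abs_Delta", "abs_Delta_bar", "abs_Delta_dbar", "sqrt_abs_Delta")) {
        v <- featureMatrix(asymmetryFeatures(co, m))
        expect_true(all(v >= 0 & v <= 1), info = m)
    }
})

test_that("external reference means can replace the pooled cohort means", {
    co <- toyCohort()
    ref <- referenceSectorMeans()
    v <- featureMatrix(asymmetryFeatures(co, "Delta_bar", refMeans = ref))
    expect_equal(unname(v[2, "TS"]), 40 / (128.1691 + 126.3527), tolerance = 1e-12)
})
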