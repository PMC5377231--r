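test_that("generation is deterministic and leaves ground truth analytic", {
    cfg <- smallConfig(seed = 9, r = 18)
    a <- generateIsletStack(cfg)
    b <- generateIsletStack(cfg)
    expect_identical(intensities(a$grid), intensities(b$grid))

    cfg40 <- syntheticConfig(rngSeed = 1, dim = c(96L, 96L, 96L),
                             spacing = c(1, 1, 1),
                             isletSemiAxes = c(40, 40, 40))
    tr <- generateIsletStack(cfg40)$truth
    expect_equal(tr@totalVolume, 4 / 3 * pi * 40^3)
    expect_equal(tr@equatorialVolume, tr@totalVolume / 2)
    expect_equal(tr@projectedArea, pi * 40^2)
})

test_that("zero granule fraction leaves only background and noise", {
    cfg <- smallConfig(seed = 3, r = 20, granuleVolumeFraction = 0)
    out <- generateIsletStack(cfg)
    islet <- maskArray(digitizeSpheroid(cfg@dim, cfg@spacing,
                                        rep(31.5, 3), rep(20, 3)))
    inside <- intensities(out$grid)[islet]
    expect_lt(max(inside),
              cfg@backgroundLevel + 5 * cfg@noiseSigma)
})

test_that("islet out of bounds and bad fractions are rejected", {
    expect_error(syntheticConfig(dim = c(32L, 32L, 32L),
                                 isletSemiAxes = c(30, 30, 30)),
                 "fit inside")
    expect_error(syntheticConfig(granuleVolumeFraction = 0.4), "0.25")
    expect_error(syntheticConfig(granuleDiameterRange = c(0.4, 0.2)),
                 "min <= max")
})

test_that("growth series scales ground truth analytically", {
    cfg <- smallConfig(seed = 2, r = 15, dim = c(72L, 72L, 72L))
    flat <- generateGrowthSeries(cfg, c(1, 1, 1), 3L)
    vols <- vapply(flat, function(s) s$truth@totalVolume, numeric(1))
    expect_equal(vols, rep(vols[1], 3))

    iso <- generateGrowthSeries(cfg, c(1.1, 1.1, 1.1), 2L)
    expect_equal(iso[[2]]$truth@totalVolume / iso[[1]]$truth@totalVolume,
                 1.1^3)

    aniso <- generateGrowthSeries(cfg, c(1.0, 1.2, 1.2), 2L)
    expect_equal(aniso[[2]]$truth@projectedArea /
                 aniso[[1]]$truth@projectedArea, 1.44)
    expect_equal(aniso[[2]]$truth@equatorialVolume /
                 aniso[[1]]$truth@equatorialVolume, 1.44)

    expect_error(generateGrowthSeries(cfg, c(0, 1, 1)), "> 0")
    expect_error(generateGrowthSeries(cfg, c(3, 3, 3), 2L), "fit inside")
})

test_that("degranulation thins granules but keeps geometry and noise", {
    cfg <- smallConfig(seed = 8, r = 16)
    same <- generateDegranulationPair(cfg, 0)
    expect_identical(intensities(same$replete$grid),
                     intensities(same$degranulated$grid))

    full <- generateDegranulationPair(cfg, 1)
    empty <- generateIsletStack(smallConfig(seed = 8, r = 16,
                                            granuleVolumeFraction = 0))
    expect_identical(intensities(full$degranulated$grid),
                     intensities(empty$grid))

    half <- generateDegranulationPair(cfg, 0.5)
    expect_equal(half$degranulated$truth@granuleVolumeFraction,
                 half$replete$truth@granuleVolumeFraction / 2)
    expect_lt(mean(intensities(half$degranulated$grid)),
              mean(intensities(half$replete$grid)))
})

test_that("top-shell intensity rises monotonically with granule fraction", {
    shellMean <- function(frac) {
        cfg <- smallConfig(seed = 4, r = 20,
                           granuleVolumeFraction = frac)
        out <- generateIsletStack(cfg)
        ctr <- rep(31.5, 3)
        islet <- maskArray(digitizeSpheroid(cfg@dim, cfg@spacing, ctr,
                                            rep(17, 3)))
        shell <- islet & upperHalf(cfg@dim, cfg@spacing, ctr[1] - 8)
        mean(intensities(out$grid)[shell])
    }
    means <- vapply(c(0.05, 0.10, 0.15, 0.20), shellMean, numeric(1))
    expect_true(all(diff(means) > 0))
})

test_that("depth attenuation follows the configured exponential", {
    cfg <- smallConfig(seed = 6, r = 26, dim = c(72L, 72L, 72L),
                       noiseSigma = 0, attenuationLength = 40)
    out <- generateIsletStack(cfg)
    ctr <- rep(35.5, 3)
    core <- maskArray(digitizeSpheroid(cfg@dim, cfg@spacing, ctr,
                                       rep(22, 3)))  # avoid blurred rim
    img <- intensities(out$grid) - cfg@backgroundLevel
    zTop <- ctr[1] - 26
    prof <- vapply(seq_len(72), function(iz) {
        sel <- core[iz, , ]
        if (sum(sel) < 50) NA_real_ else mean(img[iz, , ][sel])
    }, numeric(1))
    depth <- (seq_len(72) - 1) - zTop
    ok <- !is.na(prof) & prof > 0
    fit <- lm(log(prof[ok]) ~ depth[ok])
    expect_lt(abs(-1 / coef(fit)[2] - 40) / 40, 0.15)
})

test_that("the iris renders as a thin bright plane below the islet", {
    cfg <- smallConfig(seed = 5, r = 15, irisLevel = 400)
    out <- generateIsletStack(cfg)
    izIris <- round((31.5 + 15 + 10) / 1) + 1
    planeMeans <- apply(intensities(out$grid), 1, mean)
    expect_equal(which.max(planeMeans), izIris)
    expect_gt(planeMeans[izIris], 300)
})
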