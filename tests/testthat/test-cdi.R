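# Conservation Drop Index: window geometry, means, and invariances.

test_that("T and NT windows sit inside/outside the mature transcript", {
    cfg <- cdiConfig(window = 50, gap = 50)
    # plus-strand 3' end whose last transcribed base is 1001
    w <- cdiWindows(data.frame(chrom = "chr1", position = 1001L,
                               strand = "+", end_type = "three_prime"), cfg)
    expect_equal(c(start(w$t), end(w$t)), c(952L, 1001L))
    expect_equal(c(start(w$nt), end(w$nt)), c(1052L, 1101L))
    # minus-strand 3' end at 1001: geometry mirrors across the anchor
    w <- cdiWindows(data.frame(chrom = "chr1", position = 1001L,
                               strand = "-", end_type = "three_prime"), cfg)
    expect_equal(c(start(w$t), end(w$t)), c(1001L, 1050L))
    expect_equal(c(start(w$nt), end(w$nt)), c(901L, 950L))
    # plus-strand 5' end at 1001 matches the minus-strand 3' geometry
    w <- cdiWindows(data.frame(chrom = "chr1", position = 1001L,
                               strand = "+", end_type = "five_prime"), cfg)
    expect_equal(c(start(w$t), end(w$t)), c(1001L, 1050L))
    expect_equal(c(start(w$nt), end(w$nt)), c(901L, 950L))
    expect_false(w$truncated)
    # anchor close to the chromosome start: truncated, not an error
    w <- cdiWindows(data.frame(chrom = "chr1", position = 30L,
                               strand = "+", end_type = "three_prime"), cfg)
    expect_true(w$truncated)
    expect_equal(start(w$t), 1L)
})

test_that("CDI is the difference of window means", {
    anchor <- data.frame(chrom = "chr1", position = 1001L, strand = "+",
                         end_type = "three_prime")
    # uniform track: identical means, CDI exactly 0
    tr <- valueTrack("chr1", 1L, rep(1.7, 1200))
    expect_equal(computeCdi(anchor, tr)$cdi, 0)
    # T all 2.0, NT all -0.5 (values only where the windows are)
    tr <- ScoreTrack(GRanges("chr1", IRanges(c(952, 1052), c(1001, 1101)),
                             score = c(2.0, -0.5)), role = "conservation")
    got <- computeCdi(anchor, tr)
    expect_equal(got$cdi, 2.5)
    expect_equal(got$t_mean, 2.0)
    expect_equal(got$nt_mean, -0.5)
})

test_that("CDI matches a per-base summation oracle on random tracks", {
    set.seed(11)
    cfg <- cdiConfig()
    for (rep in 1:100) {
        # sparse random track over 1..1300 with ~70% of bases present
        present <- which(stats::runif(1300) < 0.7)
        vals <- stats::rnorm(length(present))
        valmap <- stats::setNames(vals, present)
        tr <- ScoreTrack(GRanges("chr1", IRanges(present, width = 1L),
                                 score = vals), role = "conservation")
        strand <- sample(c("+", "-"), 1)
        etype <- sample(c("three_prime", "five_prime"), 1)
        anchor <- data.frame(chrom = "chr1",
                             position = sample(200:1100, 1),
                             strand = strand, end_type = etype)
        got <- computeCdi(anchor, tr, cfg)
        w <- cdiWindows(anchor, cfg)
        t_o <- oracleMean(valmap, start(w$t), end(w$t))
        nt_o <- oracleMean(valmap, start(w$nt), end(w$nt))
        expect_equal(got$t_mean, t_o$mean, tolerance = 1e-12)
        expect_equal(got$nt_mean, nt_o$mean, tolerance = 1e-12)
        if (got$defined)
            expect_equal(got$cdi, t_o$mean - nt_o$mean, tolerance = 1e-12)
        expect_equal(got$defined,
                     !is.na(t_o$mean) && !is.na(nt_o$mean) &&
                     t_o$fraction >= 0.5 && nt_o$fraction >= 0.5)
    }
})

test_that("sparse windows below the value-fraction floor are undefined", {
    anchor <- data.frame(chrom = "chr1", position = 1001L, strand = "+",
                         end_type = "three_prime")
    # NT window has values on only 20 of 50 bases
    tr <- ScoreTrack(GRanges("chr1", IRanges(c(952, 1052), c(1001, 1071)),
                             score = c(1, 1)), role = "conservation")
    got <- computeCdi(anchor, tr)
    expect_false(got$defined)
    expect_true(is.na(got$cdi))
    expect_equal(got$nt_value_fraction, 0.4)
})

test_that("CDI is shift-invariant, scale-equivariant and mirror-invariant", {
    set.seed(3)
    L <- 2600L
    vals <- stats::rnorm(2000, sd = 1.3)
    tr <- valueTrack("chr1", 300L, vals)
    anchors <- data.frame(chrom = "chr1",
                          position = seq(500L, 1900L, by = 100L),
                          strand = rep(c("+", "-"), length.out = 15),
                          end_type = rep(c("three_prime", "five_prime"),
                                         length.out = 15))
    base <- computeCdi(anchors, tr)
    # + constant c
    tr_shift <- valueTrack("chr1", 300L, vals + 3.7)
    expect_equal(computeCdi(anchors, tr_shift)$cdi, base$cdi,
                 tolerance = 1e-10)
    # * constant k
    tr_scale <- valueTrack("chr1", 300L, vals * -2.5)
    expect_equal(computeCdi(anchors, tr_scale)$cdi, base$cdi * -2.5,
                 tolerance = 1e-10)
    # genome mirror: reflected anchors on the reflected track
    m_anchors <- data.frame(chrom = "chr1",
                            position = mirrorPos(anchors$position, L),
                            strand = flipStrand(anchors$strand),
                            end_type = anchors$end_type)
    got <- computeCdi(m_anchors, mirrorTrack(tr, L))
    expect_equal(got$cdi, base$cdi, tolerance = 1e-10)
    expect_equal(got$t_mean, base$t_mean, tolerance = 1e-10)
})

test_that("batch tables preserve order and route end types correctly", {
    tr <- valueTrack("chr1", 1L, stats::rnorm(1500))
    empty <- cdiTable(data.frame(chrom = character(0),
                                 position = integer(0),
                                 strand = character(0),
                                 end_type = character(0)), tr)
    expect_equal(nrow(empty), 0L)
    anchors <- data.frame(chrom = "chr1", position = c(800L, 800L),
                          strand = "+",
                          end_type = c("three_prime", "five_prime"))
    got <- cdiTable(anchors, tr)
    # same position, different end types: windows are mirrored, so the
    # T mean of one equals nothing in particular but geometry must differ
    expect_false(isTRUE(all.equal(got$cdi[1], got$cdi[2])))
    w3 <- cdiWindows(anchors[1, ], cdiConfig())
    w5 <- cdiWindows(anchors[2, ], cdiConfig())
    # both end types anchor the T window on the transcribed base itself,
    # with the windows reflected across it
    expect_equal(start(w5$t), end(w3$t))
    expect_equal(c(start(w5$nt), end(w5$nt)), c(700L, 749L))
    expect_equal(c(start(w3$nt), end(w3$nt)), c(851L, 900L))
})

test_that("planted PASs score high CDIs and recover the conservation drop", {
    sc <- strongScenario()
    truth <- sc$truth
    g <- truth[truth$record == "gene" & !is.na(truth$true_pas), ]
    anchors <- data.frame(chrom = g$chrom, position = g$true_pas,
                          strand = g$strand, end_type = "three_prime")
    got <- computeCdi(anchors, sc$conservation)
    expect_true(all(got$defined))
    drop <- sc$config$mu_in - sc$config$mu_out
    # mean CDI ~ N(drop, sigma * sqrt(2/50) per site); 3 SE over n sites
    se <- sc$config$sigma * sqrt(2 / 50) / sqrt(nrow(got))
    expect_lt(abs(mean(got$cdi) - drop), 3 * se)
    # TSS anchors see uniform conservation: CDI centred at 0, so the
    # planted-PAS mean is strictly higher
    tss <- computeCdi(data.frame(chrom = g$chrom, position = g$tss,
                                 strand = g$strand,
                                 end_type = "five_prime"),
                      sc$conservation)
    expect_gt(mean(got$cdi), mean(tss$cdi))
})

test_that("a null generator (no conservation drop) centres CDI at zero", {
    cfg <- scenarioConfig(seed = 202L, mu_in = 1.0, mu_out = 1.0)
    sc <- generateScenario(cfg)
    g <- sc$truth[sc$truth$record == "gene" & !is.na(sc$truth$true_pas), ]
    got <- computeCdi(data.frame(chrom = g$chrom, position = g$true_pas,
                                 strand = g$strand,
                                 end_type = "three_prime"),
                      sc$conservation)
    se <- stats::sd(got$cdi) / sqrt(nrow(got))
    expect_lt(abs(mean(got$cdi)), 3 * se)
})

test_that("histogram binning can blank the central band", {
    df <- data.frame(cdi = c(-1, -0.4, 0.1, 0.3, 0.8, 1.2, NA))
    h <- cdiHistogram(df, binwidth = 0.5)
    expect_equal(sum(h$count), 6L)
    h2 <- cdiHistogram(df, binwidth = 0.5, exclude_band = 0.5)
    expect_equal(sum(h2$count), 3L)
})
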