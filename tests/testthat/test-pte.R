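# EST-extreme clustering, proximity merging, filtering and classification.

test_that("extremes chain by single linkage with modal representatives", {
    cl <- clusterEstEnds(data.frame(chrom = "chr1",
                                    pos = c(100L, 100L, 101L)))
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$support, 3L)
    expect_equal(cl$position, 100L)
    # gap of 2 exceeds the 1-nt linkage
    cl <- clusterEstEnds(data.frame(chrom = "chr1", pos = c(100L, 102L)))
    expect_equal(nrow(cl), 2L)
    expect_equal(cl$support, c(1L, 1L))
    # modal tie resolves to the larger coordinate
    cl <- clusterEstEnds(data.frame(chrom = "chr1",
                                    pos = c(200L, 200L, 201L, 201L)))
    expect_equal(cl$position, 201L)
    # chaining is transitive: 100,101,102 form one cluster
    cl <- clusterEstEnds(data.frame(chrom = "chr1", pos = 100:102))
    expect_equal(nrow(cl), 1L)
    expect_equal(clusterEstEnds(data.frame(chrom = character(0),
                                           pos = integer(0))),
                 clusterEstEnds(data.frame(chrom = character(0),
                                           pos = integer(0))))
})

test_that("clustering agrees with an O(n^2) union-find oracle", {
    set.seed(42)
    for (rep in 1:5) {
        pos <- sample.int(2000L, 500L, replace = TRUE)
        got <- clusterEstEnds(data.frame(chrom = "chr1", pos = pos))
        want <- oracleCluster(pos, link = 1L)
        expect_equal(got$position, want$position)
        expect_equal(got$support, want$support)
        expect_equal(got$min_pos, want$min_pos)
        expect_equal(got$max_pos, want$max_pos)
    }
})

test_that("proximal clusters collapse to the transcription-distal one", {
    clusters <- data.frame(chrom = "chr1", position = c(100L, 110L),
                           support = c(5L, 5L),
                           min_pos = c(100L, 110L),
                           max_pos = c(100L, 110L))
    plus_up <- txModel("t1", "chr1", "+", c(1, 50))
    got <- mergeProximalClusters(clusters, plus_up)
    expect_equal(got$position, 110L)
    # strand mirror: minus-strand gene downstream keeps the smaller one
    minus_down <- txModel("t1", "chr1", "-", c(200, 400))
    got <- mergeProximalClusters(clusters, minus_down)
    expect_equal(got$position, 100L)
    # no gene in range: highest support wins across the <25-nt chain
    chain <- data.frame(chrom = "chr1",
                        position = c(100L, 120L, 139L) + 5000000L,
                        support = c(5L, 9L, 4L),
                        min_pos = c(100L, 120L, 139L) + 5000000L,
                        max_pos = c(100L, 120L, 139L) + 5000000L)
    got <- mergeProximalClusters(chain, plus_up)
    expect_equal(got$support, 9L)
    # a 30-nt gap breaks the chain: two independent runs survive
    chain$position <- c(100L, 120L, 150L) + 5000000L
    chain$min_pos <- chain$position; chain$max_pos <- chain$position
    got <- mergeProximalClusters(chain, plus_up)
    expect_equal(got$support, c(9L, 4L))
})

test_that("merging is idempotent and leaves >= merge_distance gaps", {
    ref <- combineTx(txModel("t1", "chr1", "+", c(1000, 2000)),
                     txModel("t2", "chr1", "-", c(9000, 9500)))
    set.seed(7)
    for (rep in 1:10) {
        pos <- sort(sample.int(12000L, 80L))
        cl <- clusterEstEnds(data.frame(chrom = "chr1", pos = pos))
        m1 <- mergeProximalClusters(cl, ref)
        expect_true(all(diff(m1$position) >= 25L))
        m2 <- mergeProximalClusters(m1, ref)
        expect_identical(m1, m2)
    }
})

test_that("support, exon and splice-site filters apply as stated", {
    ref <- txModel("t1", "chr1", "+", c(1000, 2000), c(3000, 4000))
    ests <- estModel(c("sp", "sp"), "chr1",
                     starts = c(10000L, 10500L), ends = c(10100L, 10600L))
    mk <- function(pos, support) {
        data.frame(chrom = "chr1", position = pos, support = support,
                   min_pos = pos, max_pos = pos)
    }
    # support below 4 is removed
    expect_equal(nrow(filterPtes(mk(500L, 3L), ref, ests)), 0L)
    expect_equal(nrow(filterPtes(mk(500L, 4L), ref, ests)), 1L)
    # inside an annotated exon: removed; inside the intron: kept
    expect_equal(nrow(filterPtes(mk(1500L, 10L), ref, ests)), 0L)
    expect_equal(nrow(filterPtes(mk(2500L, 10L), ref, ests)), 1L)
    # splice sites at 10100 and 10500: 25 nt away removed, 26 kept
    expect_equal(nrow(filterPtes(mk(10125L, 10L), ref, ests)), 0L)
    expect_equal(nrow(filterPtes(mk(10126L, 10L), ref, ests)), 1L)
})

test_that("orientation of the closest gene sets the putative identity", {
    mk <- function(pos) data.frame(chrom = "chr1", position = pos,
                                   support = 5L, min_pos = pos,
                                   max_pos = pos)
    gene_left <- txModel("t1", "chr1", "+", c(1, 500), c(800, 1000))
    # plus-strand gene upstream is transcribed towards the PTE
    got <- classifyPtes(mk(3001L), gene_left)
    expect_equal(got$identity, "putative_PAS")
    expect_equal(got$inferred_strand, "+")
    expect_equal(got$distance, 2001L)
    # plus-strand gene downstream is transcribed away
    gene_right <- txModel("t1", "chr1", "+", c(5001, 8000))
    got <- classifyPtes(mk(3001L), gene_right)
    expect_equal(got$identity, "putative_TSS")
    # genes beyond 1 Mb are ignored
    got <- classifyPtes(mk(3001L + 2000000L), gene_left)
    expect_equal(got$identity, "undetermined")
    # containment in introns of opposite-strand transcripts
    both <- combineTx(txModel("a", "chr1", "+", c(1, 100), c(901, 1000)),
                      txModel("b", "chr1", "-", c(1, 100), c(901, 1000)))
    got <- classifyPtes(mk(500L), both)
    expect_equal(got$identity, "undetermined")
    expect_equal(got$distance, 0L)
})

test_that("classification ignores transcript list order", {
    ref1 <- combineTx(txModel("a", "chr1", "+", c(1, 1000)),
                      txModel("b", "chr1", "-", c(4000, 5000)))
    ref2 <- combineTx(txModel("b", "chr1", "-", c(4000, 5000)),
                      txModel("a", "chr1", "+", c(1, 1000)))
    pte <- data.frame(chrom = "chr1", position = c(2000L, 2600L, 6000L),
                      support = 5L, min_pos = c(2000L, 2600L, 6000L),
                      max_pos = c(2000L, 2600L, 6000L))
    g1 <- classifyPtes(pte, ref1)
    g2 <- classifyPtes(pte, ref2)
    expect_identical(g1$identity, g2$identity)
    expect_identical(g1$nearest_transcript, g2$nearest_transcript)
    # both genes converge on the PTEs between them: PAS from both sides
    expect_equal(g1$identity[1:2], c("putative_PAS", "putative_PAS"))
})

test_that("every well-supported planted PAS survives as one cluster", {
    sc <- strongScenario()
    ptes <- strongPtes()
    extr <- estExtremes(sc$ests)
    sites <- sc$truth[sc$truth$record == "gene" &
                      !is.na(sc$truth$true_pas), ]
    for (i in seq_len(nrow(sites))) {
        p <- sites$true_pas[i]
        n_ends <- sum(abs(extr$pos - p) <= 1L)
        if (n_ends < 4L) next
        hits <- which(abs(ptes$position - p) <= 1L)
        expect_length(hits, 1L)
    }
})

test_that("genome mirroring preserves PAS and TSS labels", {
    L <- 20000L
    ref <- combineTx(txModel("a", "chr1", "+", c(2000, 2400), c(3000, 3600)),
                     txModel("b", "chr1", "-", c(9000, 9300), c(9800, 10000)))
    ests <- estModel(rep(c("e1", "e2", "e3", "e4", "e5"), each = 1),
                     "chr1",
                     starts = c(4500L, 4501L, 4500L, 4500L, 7000L),
                     ends = c(4900L, 4900L, 4901L, 4899L, 8500L))
    fwd <- detectPtes(ests, ref)
    rev <- detectPtes(mirrorEsts(ests, L), mirrorTx(ref, L))
    expect_equal(nrow(fwd), nrow(rev))
    ord_f <- order(fwd$position)
    ord_r <- order(-rev$position)  # mirrored coordinates reverse order
    expect_equal(fwd$identity[ord_f], rev$identity[ord_r])
    expect_equal(mirrorPos(fwd$position[ord_f], L), rev$position[ord_r])
    expect_equal(fwd$support[ord_f], rev$support[ord_r])
})
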