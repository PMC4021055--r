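exampleCalls <- system.file("extdata", "example_calls.tsv",
                            package = "CNVconcord")

test_that("call tables group by (sample, program), derive status and drop non-autosomes", {
    sets <- readCallTable(exampleCalls)
    expect_s4_class(sets, "CNVCallSetList")
    ## 10 rows, 1 on X -> 9 calls over 4 (sample, program) groups
    expect_identical(metadata(sets)$excludedRows, 1L)
    expect_setequal(names(sets), c("S1|PC", "S1|AGC", "S2|PC", "S2|AGC"))
    expect_identical(length(sets[["S1|PC"]]), 3L)
    expect_identical(length(sets[["S1|AGC"]]), 2L)
    s2pc <- cnvCalls(sets[["S2|PC"]])
    expect_identical(mcols(s2pc)$status, c("LOSS", "GAIN"))
    expect_identical(mcols(s2pc)$state, c(1L, 4L))
    expect_true(all(mcols(cnvCalls(sets[["S2|AGC"]]))$mergedFrom == 1L))
})

test_that("malformed call tables raise named, row-level errors", {
    write_tbl <- function(lines) {
        f <- tempfile(fileext = ".tsv")
        writeLines(lines, f)
        f
    }
    expect_error(
        readCallTable(write_tbl(c("sample_id\tprogram_id\tchrom\tstart\tend",
                                  "S1\tPC\t1\t1\t2"))),
        "mandatory column 'state'")
    expect_error(
        readCallTable(write_tbl(c("sample_id\tprogram_id\tchrom\tstart\tend\tstate",
                                  "S1\tPC\t1\t1.5\t200\t1"))),
        "non-integer start coordinate in row\\(s\\) 2")
    expect_error(
        readCallTable(write_tbl(c("sample_id\tprogram_id\tchrom\tstart\tend\tstate",
                                  "S1\tPC\t1\t100\t200\t5"))),
        "invalid copy-number state")
    expect_error(
        readCallTable(write_tbl(c("sample_id\tprogram_id\tchrom\tstart\tend\tstate",
                                  "S1\tPC\t1\t300\t200\t1"))),
        "end < start in row\\(s\\) 2")
    ## "4+" is legal shorthand for state 4
    ok <- readCallTable(write_tbl(c("sample_id\tprogram_id\tchrom\tstart\tend\tstate",
                                    "S1\tPC\t1\t100\t2000\t4+")))
    expect_identical(mcols(cnvCalls(ok[[1L]]))$state, 4L)
})

test_that("write/read round trip preserves every field", {
    sets <- readCallTable(exampleCalls)
    f <- tempfile(fileext = ".tsv")
    writeCallTable(sets, f)
    back <- readCallTable(f)
    expect_setequal(names(back), names(sets))
    for (k in names(sets))
        expect_identical(callFrame(back[[k]]), callFrame(sets[[k]]))
    ## marker counts survive too
    expect_identical(mcols(cnvCalls(back[["S1|PC"]]))$nMarkers,
                     mcols(cnvCalls(sets[["S1|PC"]]))$nMarkers)
})

test_that("BED interchange converts coordinates and survives a round trip", {
    sets <- readCallTable(exampleCalls)
    f <- tempfile(fileext = ".bed")
    exportBED(sets[["S1|PC"]], f)
    raw <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
    ## BED is 0-based half-open: starts shift by one, ends unchanged
    gr <- cnvCalls(sets[["S1|PC"]])
    expect_identical(sort(raw$V2), sort(start(gr) - 1L))
    expect_identical(sort(raw$V3), sort(end(gr)))
    back <- importBED(f)
    expect_identical(callFrame(back[[1L]]), callFrame(sets[["S1|PC"]]))
})

test_that("inclusion filters apply marker, strict-length and neutral rules", {
    cs <- CNVCallSet("S", "P", GRanges("1",
        IRanges(c(1000, 20000, 40000, 60000),
                c(5999, 20999, 41000, 70000)),
        state = c(1L, 3L, 0L, 2L),
        nMarkers = c(9L, 12L, 10L, 50L)))
    out <- filterCalls(cs)
    df <- callFrame(out)
    ## 9 markers -> dropped; length exactly 1000 -> dropped (strict > 1 kb);
    ## length 1001 with 10 markers -> kept; neutral -> dropped
    expect_identical(nrow(df), 1L)
    expect_identical(df$start, 40000L)
    drops <- metadata(out)$filterDrops
    expect_identical(drops, c(markers = 1L, length = 1L, neutral = 1L,
                              retained = 1L))
    expect_identical(sum(drops), length(cs))
    ## idempotent
    again <- filterCalls(out)
    expect_identical(callFrame(again), df)
    expect_identical(metadata(again)$filterDrops[["retained"]], 1L)
})

test_that("marker filter demands marker counts", {
    cs <- CNVCallSet("S", "P", GRanges("1", IRanges(1000, 9999), state = 1L))
    expect_error(filterCalls(cs), "minMarkers = 0")
    expect_identical(length(filterCalls(cs, minMarkers = 0)), 1L)
})

test_that("relatedness pairs acquire expected sharing and are validated", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("sample_a\tsample_b\trelation",
                 "T1a\tT1b\tMZ", "P1\tT2a\tparent_child", "T1a\tT4a\tunrelated"),
               f)
    p <- readPairs(f)
    expect_identical(p$expected_sharing, c(1.0, 0.5, 0.0))
    expect_error(validatePairs(data.frame(sample_a = "A", sample_b = "A",
                                          relation = "MZ")), "self-pair")
    expect_error(validatePairs(data.frame(sample_a = c("A", "B"),
                                          sample_b = c("B", "A"),
                                          relation = "MZ")), "duplicate")
    expect_error(validatePairs(data.frame(sample_a = "A", sample_b = "B",
                                          relation = "sibling")),
                 "unknown relation 'sibling'; allowed: MZ, parent_child, unrelated")
})
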