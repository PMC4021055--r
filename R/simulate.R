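#' Default autosome model
#'
#' Autosome lengths (bp) approximating the human genome (GRCh37 scale),
#' chromosomes "1".."22". Used for CNV placement and for chromosome-size
#' proportionality of the simulated chromosomal distribution.
#'
#' @return named numeric vector of 22 autosome lengths.
#' @export
defaultGenome <- function() {
    mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
            135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
    stats::setNames(mb * 1e6, as.character(1:22))
}

#' Default study-like pedigree
#'
#' Sixteen individuals: six monozygotic twin pairs plus the two parents for
#' twin pairs 2 and 3. Twins of pairs 1, 4, 5, 6 and all parents are
#' founders; the primary twin of pairs 2 and 3 is a child of their parents,
#' and the co-twin is genetically identical to the primary twin.
#'
#' @return data.frame with columns `id`, `father`, `mother`, `twinOf`.
#' @export
defaultPedigree <- function() {
    ids <- c(paste0("T", rep(1:6, each = 2), rep(c("a", "b"), 6)),
             "P2f", "P2m", "P3f", "P3m")
    ped <- data.frame(id = ids, father = NA_character_,
                      mother = NA_character_, twinOf = NA_character_,
                      stringsAsFactors = FALSE)
    ped$twinOf[ped$id %in% paste0("T", 1:6, "b")] <- paste0("T", 1:6, "a")
    ped[ped$id == "T2a", c("father", "mother")] <- c("P2f", "P2m")
    ped[ped$id == "T3a", c("father", "mother")] <- c("P3f", "P3m")
    ped
}

#' Default caller error profiles
#'
#' Four profiles spanning the behaviours seen when several programs call
#' CNVs on the same arrays: three HMM-like callers with similar sensitivity
#' and modest false-positive load (yielding on the order of 80 calls per
#' individual with the default 80 true CNVs per founder), and one
#' segmentation-like caller dominated by caller-specific false positives
#' (on the order of 310 calls per individual, hence little overlap with
#' the others).
#'
#' @return named list of [CallerProfile] objects.
#' @export
defaultCallerProfiles <- function() {
    list(AGC = callerProfile("AGC", sensitivity = 0.92, fpRate = 8,
                             jitterSd = 2000, fragProb = 0.05,
                             stateFlipProb = 0.01),
         PGS = callerProfile("PGS", sensitivity = 0.88, fpRate = 10,
                             jitterSd = 3000, fragProb = 0.08,
                             stateFlipProb = 0.02),
         PC = callerProfile("PC", sensitivity = 0.90, fpRate = 6,
                            jitterSd = 1500, fragProb = 0.05,
                            stateFlipProb = 0.01),
         GH = callerProfile("GH", sensitivity = 0.85, fpRate = 240,
                            jitterSd = 5000, fragProb = 0.10,
                            stateFlipProb = 0.05))
}

#' Configuration of a simulated cohort
#'
#' Bundles the genome model, the pedigree, the truth-model parameters and
#' the caller error profiles. Founders draw `nCnvsPerFounder` true CNVs
#' (log-uniform lengths over `lengthRange`, uniform placement, no
#' within-individual overlap), each a heterozygous gain (state 3) or loss
#' (state 1) with equal probability. A `populationSharedFraction` of the
#' per-founder count is drawn once as common polymorphic loci carried by
#' every founder. MZ co-twins replicate their twin exactly (plus
#' `deNovoPerTwin` private events, default 0); children inherit each
#' parental CNV independently with probability 0.5.
#'
#' @param genome named autosome lengths, see [defaultGenome()].
#' @param pedigree data.frame (`id`, `father`, `mother`, `twinOf`), see
#'   [defaultPedigree()].
#' @param nCnvsPerFounder true CNVs per founder (default 80, the scale of
#'   the HMM callers' per-individual call counts).
#' @param lengthRange bp range of the log-uniform CNV length distribution,
#'   default 2 kb to 5 Mb.
#' @param populationSharedFraction fraction of loci common to all founders,
#'   default 0.1.
#' @param deNovoPerTwin expected somatic de novo CNVs private to each MZ
#'   co-twin (Poisson mean), default 0.
#' @param callerProfiles list of [CallerProfile]s, see
#'   [defaultCallerProfiles()].
#' @param seed integer seed governing every random draw.
#' @return a `SimConfig`.
#' @export
simConfig <- function(genome = defaultGenome(), pedigree = defaultPedigree(),
                      nCnvsPerFounder = 80, lengthRange = c(2e3, 5e6),
                      populationSharedFraction = 0.1, deNovoPerTwin = 0,
                      callerProfiles = defaultCallerProfiles(), seed = 1L) {
    new("SimConfig", genome = genome, pedigree = pedigree,
        nCnvsPerFounder = as.integer(nCnvsPerFounder),
        lengthRange = as.numeric(lengthRange),
        populationSharedFraction = populationSharedFraction,
        deNovoPerTwin = deNovoPerTwin,
        callerProfiles = callerProfiles, seed = as.integer(seed))
}

## Draw n non-overlapping loci on the genome: chromosome chosen with
## probability proportional to length, start uniform. 'avoid' holds loci
## already owned by the individual. Bounded rejection.
.drawLoci <- function(n, genome, lengthRange, avoid = GRanges()) {
    chromNames <- names(genome)
    ## per-chromosome occupied intervals as plain vectors
    avChrom <- as.character(seqnames(avoid))
    occS <- lapply(stats::setNames(chromNames, chromNames),
                   function(ch) start(avoid)[avChrom == ch])
    occE <- lapply(stats::setNames(chromNames, chromNames),
                   function(ch) end(avoid)[avChrom == ch])
    outChrom <- character(n); outS <- numeric(n); outE <- numeric(n)
    placed <- 0L
    tries <- 0L
    maxTries <- 200L * max(1L, n)
    while (placed < n) {
        if ((tries <- tries + 1L) > maxTries)
            stop("genome too small to place the requested CNVs without overlap")
        len <- round(exp(stats::runif(1, log(lengthRange[1]),
                                      log(lengthRange[2]))))
        chrom <- sample(chromNames, 1L, prob = genome)
        maxStart <- genome[[chrom]] - len + 1
        if (maxStart < 1) next
        s <- floor(stats::runif(1, 1, maxStart + 1))
        e <- s + len - 1
        if (any(s <= occE[[chrom]] & e >= occS[[chrom]])) next
        placed <- placed + 1L
        outChrom[placed] <- chrom; outS[placed] <- s; outE[placed] <- e
        occS[[chrom]] <- c(occS[[chrom]], s)
        occE[[chrom]] <- c(occE[[chrom]], e)
    }
    GRanges(factor(outChrom, levels = chromNames), IRanges(outS, outE))
}

.truthGR <- function(loci, status, locusId) {
    mcols(loci)$state <- ifelse(status == "GAIN", 3L, 1L)
    mcols(loci)$status <- status
    mcols(loci)$locusId <- locusId
    loci
}

#' Simulate the true CNV complement of a pedigree
#'
#' Generates per-individual true CNV sets respecting the pedigree:
#' founders draw independent loci (plus the population-shared loci common
#' to all founders), MZ co-twins copy their twin exactly, children inherit
#' each parental CNV independently with probability 0.5. Inherited and
#' shared CNVs keep a cohort-wide `locusId`, so identity-by-descent is
#' traceable. Within an individual, true CNVs never overlap (an inherited
#' locus colliding with an already-owned one is dropped).
#'
#' @param cfg a [simConfig()].
#' @return named list of `GRanges`, one per pedigree id, each with
#'   metadata columns `state`, `status`, `locusId`.
#' @export
simulateTruthCohort <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(cfg@seed)
    ped <- cfg@pedigree
    genome <- cfg@genome
    nShared <- round(cfg@populationSharedFraction * cfg@nCnvsPerFounder)
    nPrivate <- cfg@nCnvsPerFounder - nShared
    nextLocus <- 0L
    newIds <- function(k) {
        ids <- nextLocus + seq_len(k)
        nextLocus <<- nextLocus + k
        ids
    }
    sharedLoci <- .drawLoci(nShared, genome, cfg@lengthRange)
    shared <- .truthGR(sharedLoci,
                       sample(c("GAIN", "LOSS"), nShared, replace = TRUE),
                       newIds(nShared))
    truth <- list()
    isFounder <- is.na(ped$father) & is.na(ped$mother) & is.na(ped$twinOf)
    for (id in ped$id[isFounder]) {
        private <- .drawLoci(nPrivate, genome, cfg@lengthRange,
                             avoid = S4Vectors::`mcols<-`(shared, value = NULL))
        gr <- c(shared, .truthGR(private,
                                 sample(c("GAIN", "LOSS"), nPrivate,
                                        replace = TRUE),
                                 newIds(nPrivate)))
        truth[[id]] <- sort(gr)
    }
    isChild <- !is.na(ped$father)
    for (id in ped$id[isChild]) {
        fa <- truth[[ped$father[ped$id == id]]]
        mo <- truth[[ped$mother[ped$id == id]]]
        ## common polymorphic loci are carried by both parents; transmit once
        moPrivate <- mo[!mcols(mo)$locusId %in% mcols(fa)$locusId]
        inherited <- c(fa[stats::runif(length(fa)) < 0.5],
                       moPrivate[stats::runif(length(moPrivate)) < 0.5])
        if (length(inherited) > 1L) {
            drop <- unique(S4Vectors::queryHits(
                findOverlaps(inherited, drop.self = TRUE,
                             drop.redundant = TRUE, ignore.strand = TRUE)))
            if (length(drop)) inherited <- inherited[-drop]
        }
        truth[[id]] <- sort(inherited)
    }
    isTwin <- !is.na(ped$twinOf)
    for (id in ped$id[isTwin]) {
        base <- truth[[ped$twinOf[ped$id == id]]]
        if (cfg@deNovoPerTwin > 0) {
            k <- stats::rpois(1L, cfg@deNovoPerTwin)
            if (k > 0L) {
                dn <- .drawLoci(k, genome, cfg@lengthRange,
                                avoid = S4Vectors::`mcols<-`(base, value = NULL))
                base <- c(base, .truthGR(dn, sample(c("GAIN", "LOSS"), k,
                                                    replace = TRUE),
                                         newIds(k)))
            }
        }
        truth[[id]] <- sort(base)
    }
    truth[ped$id]
}

#' Pass a true CNV set through a caller error model
#'
#' Each true CNV is detected with probability `sensitivity`. Detected calls
#' get independent Gaussian breakpoint jitter (sd `jitterSd`, clamped to
#' chromosome bounds, minimum emitted length 1001 bp so the >1 kb filter is
#' satisfiable), have their gain/loss status inverted with probability
#' `stateFlipProb`, and are emitted as two fragments with probability
#' `fragProb` when long enough that both fragments exceed 1 kb — the
#' separating gap is at most 15% of the call span, within reach of the
#' default 20% merge rule. `Poisson(fpRate)` false-positive calls are
#' placed uniformly with the configured length distribution. Marker counts
#' are synthesized at one marker per kb (minimum 10), so default filters
#' retain every emitted call.
#'
#' @param truth `GRanges` of true CNVs for one individual
#'   (from [simulateTruthCohort()]).
#' @param profile a [callerProfile()].
#' @param genome named autosome lengths.
#' @param sampleIdentifier sample id for the emitted [CNVCallSet].
#' @param seed integer seed for this (individual, caller) draw.
#' @param lengthRange length distribution for false-positive calls.
#' @return a [CNVCallSet]; `metadata()$trace` is a data.frame (`locusId`,
#'   `fragment`), parallel to the sorted calls, tracing each emitted call
#'   back to its true locus (`NA` locus for false positives).
#' @export
applyCaller <- function(truth, profile, genome, sampleIdentifier, seed,
                        lengthRange = c(2e3, 5e6)) {
    stopifnot(is(profile, "CallerProfile"))
    set.seed(as.integer(seed))
    df <- .callerEmissions(truth, profile, genome, lengthRange)
    if (!nrow(df)) {
        cs <- CNVCallSet(sampleIdentifier, profile@programId)
        metadata(cs)$trace <- data.frame(locusId = integer(),
                                         fragment = logical())
        return(cs)
    }
    state <- ifelse(df$status == "GAIN", 3L, 1L)
    ## canonical sort order of the emitted call set
    ord <- order(as.integer(df$chrom), df$start, df$end, df$status)
    gr <- GRanges(factor(df$chrom[ord], levels = names(genome)),
                  IRanges(df$start[ord], df$end[ord]))
    mcols(gr) <- DataFrame(
        state = state[ord],
        nMarkers = pmax(10L, as.integer(
            round((df$end - df$start + 1) / 1000)))[ord],
        status = df$status[ord],
        mergedFrom = rep(1L, nrow(df)))
    cs <- .newCallSet(sampleIdentifier, profile@programId, gr)
    metadata(cs)$trace <- data.frame(locusId = df$locusId[ord],
                                     fragment = df$fragment[ord])
    cs
}

#' Simulate a full multi-caller dataset over a pedigree
#'
#' Runs [simulateTruthCohort()] and then [applyCaller()] for every
#' (individual, caller profile), deriving one reproducible sub-seed per
#' combination from `cfg@seed`. Also enumerates the relatedness pairs the
#' pedigree implies: every MZ twin pair, every parent-child pair, and
#' unrelated pairs taken across families.
#'
#' @param cfg a [simConfig()].
#' @param outdir optional directory; when given, writes `calls.tsv`
#'   ([writeCallTable()] layout), `pairs.tsv` and `truth.tsv` there.
#' @param maxUnrelated cap on the number of enumerated unrelated pairs
#'   (default 12); the study design used three.
#' @return list with `callSets` (a [CNVCallSetList]), `pairs` (validated
#'   data.frame), `truth` (named list of `GRanges`), and `trace` (per-call
#'   locus/fragment provenance, parallel to `callSets`).
#' @export
simulateDataset <- function(cfg, outdir = NULL, maxUnrelated = 12L) {
    stopifnot(is(cfg, "SimConfig"))
    truth <- simulateTruthCohort(cfg)
    ids <- names(truth)
    sets <- list()
    trace <- list()
    for (pi in seq_along(cfg@callerProfiles)) {
        profile <- cfg@callerProfiles[[pi]]
        for (si in seq_along(ids)) {
            sub <- (cfg@seed %% 100000L) * 10000L + pi * 1000L + si
            key <- paste(ids[si], profile@programId, sep = "|")
            cs <- applyCaller(truth[[ids[si]]], profile, cfg@genome,
                              ids[si], sub, cfg@lengthRange)
            trace[[key]] <- metadata(cs)$trace
            sets[[key]] <- cs
        }
    }
    pairs <- .enumeratePairs(cfg@pedigree, maxUnrelated = maxUnrelated)
    out <- list(callSets = CNVCallSetList(sets), pairs = pairs,
                truth = truth, trace = trace)
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        writeCallTable(out$callSets, file.path(outdir, "calls.tsv"))
        writePairs(pairs, file.path(outdir, "pairs.tsv"))
        truthDf <- do.call(rbind, lapply(ids, function(id) {
            gr <- truth[[id]]
            if (!length(gr)) return(NULL)
            data.frame(sample_id = id, chrom = as.character(seqnames(gr)),
                       start = start(gr), end = end(gr),
                       state = mcols(gr)$state, status = mcols(gr)$status,
                       locus_id = mcols(gr)$locusId, stringsAsFactors = FALSE)
        }))
        utils::write.table(truthDf, file.path(outdir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}

## Emission engine shared by applyCaller: one row per emitted call, in
## emission order, with truth provenance (locusId, fragment).
.callerEmissions <- function(truth, profile, genome, lengthRange) {
    nT <- length(truth)
    tChrom <- as.character(seqnames(truth))
    tStart <- start(truth); tEnd <- end(truth)
    tStatus <- mcols(truth)$status
    tLocus <- mcols(truth)$locusId
    cap <- 2L * nT + 64L
    oChrom <- character(cap); oS <- numeric(cap); oE <- numeric(cap)
    oStatus <- character(cap); oLocus <- integer(cap); oFrag <- logical(cap)
    k <- 0L
    emit <- function(chrom, s, e, status, locusId, fragment) {
        k <<- k + 1L
        if (k > length(oS)) {   # grow for false-positive overflow
            oChrom <<- c(oChrom, character(cap)); oS <<- c(oS, numeric(cap))
            oE <<- c(oE, numeric(cap)); oStatus <<- c(oStatus, character(cap))
            oLocus <<- c(oLocus, integer(cap)); oFrag <<- c(oFrag, logical(cap))
        }
        oChrom[k] <<- chrom; oS[k] <<- s; oE[k] <<- e
        oStatus[k] <<- status; oLocus[k] <<- locusId; oFrag[k] <<- fragment
    }
    minLen <- 1001L
    for (i in seq_len(nT)) {
        if (stats::runif(1) > profile@sensitivity) next
        chrom <- tChrom[i]
        chromLen <- genome[[chrom]]
        s <- tStart[i]; e <- tEnd[i]
        if (profile@jitterSd > 0) {
            s <- round(s + stats::rnorm(1, 0, profile@jitterSd))
            e <- round(e + stats::rnorm(1, 0, profile@jitterSd))
        }
        s <- min(max(1, s), chromLen)
        e <- min(max(1, e), chromLen)
        if (e < s) { m <- s; s <- e; e <- m }
        if (e - s + 1 < minLen) e <- min(chromLen, s + minLen - 1)
        status <- tStatus[i]
        if (stats::runif(1) < profile@stateFlipProb)
            status <- if (status == "GAIN") "LOSS" else "GAIN"
        span <- e - s + 1
        if (stats::runif(1) < profile@fragProb && span >= 2 * minLen / 0.85) {
            gap <- max(1L, round(stats::runif(1, 0.02, 0.15) * span))
            leftLen <- round(stats::runif(1, minLen, span - gap - minLen))
            emit(chrom, s, s + leftLen - 1, status, tLocus[i], TRUE)
            emit(chrom, s + leftLen + gap, e, status, tLocus[i], TRUE)
        } else {
            emit(chrom, s, e, status, tLocus[i], FALSE)
        }
    }
    nFp <- stats::rpois(1L, profile@fpRate)
    for (f in seq_len(nFp)) {
        len <- max(minLen, round(exp(stats::runif(1, log(lengthRange[1]),
                                                  log(lengthRange[2])))))
        chrom <- sample(names(genome), 1L, prob = genome)
        maxStart <- genome[[chrom]] - len + 1
        if (maxStart < 1) next
        s <- floor(stats::runif(1, 1, maxStart + 1))
        emit(chrom, s, s + len - 1, sample(c("GAIN", "LOSS"), 1L),
             NA_integer_, FALSE)
    }
    data.frame(chrom = oChrom[seq_len(k)], start = oS[seq_len(k)],
               end = oE[seq_len(k)], status = oStatus[seq_len(k)],
               locusId = oLocus[seq_len(k)], fragment = oFrag[seq_len(k)],
               stringsAsFactors = FALSE)
}

.enumeratePairs <- function(ped, maxUnrelated = 12L) {
    rows <- list()
    add <- function(a, b, rel) rows[[length(rows) + 1L]] <<-
        data.frame(sample_a = a, sample_b = b, relation = rel,
                   stringsAsFactors = FALSE)
    twins <- ped[!is.na(ped$twinOf), ]
    for (r in seq_len(nrow(twins)))
        add(twins$twinOf[r], twins$id[r], "MZ")
    ## family membership: the founder "root" each individual descends from
    famOf <- function(id) {
        row <- ped[ped$id == id, ]
        if (!is.na(row$twinOf)) return(famOf(row$twinOf))
        if (!is.na(row$father)) return(famOf(row$father))
        id
    }
    fam <- vapply(ped$id, famOf, character(1))
    ## parent-child: each child (and its MZ co-twin) against each parent
    kids <- ped[!is.na(ped$father), ]
    for (r in seq_len(nrow(kids))) {
        co <- ped$id[!is.na(ped$twinOf) & ped$twinOf == kids$id[r]]
        for (k in c(kids$id[r], co)) {
            add(kids$father[r], k, "parent_child")
            add(kids$mother[r], k, "parent_child")
        }
    }
    ## spouses share a family root label through their child; fix: parents
    ## are their own roots
    founders <- ped$id[is.na(ped$father) & is.na(ped$twinOf)]
    if (length(founders) > 1L) {
        cmb <- utils::combn(founders, 2L)
        n <- 0L
        for (cidx in seq_len(ncol(cmb))) {
            a <- cmb[1L, cidx]; b <- cmb[2L, cidx]
            ## exclude spouse pairs (shared offspring) to keep groups clean
            mates <- any((ped$father %in% a & ped$mother %in% b) |
                         (ped$father %in% b & ped$mother %in% a))
            if (mates) next
            if (fam[[a]] == fam[[b]]) next
            add(a, b, "unrelated")
            if ((n <- n + 1L) >= maxUnrelated) break
        }
    }
    validatePairs(do.call(rbind, rows))
}
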