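# Synthetic data with machine-readable ground truth: genomes with planted
# pre-miRNA hairpins, multi-sample adapter-tagged read libraries, ncRNA
# decoys, a known-miRNA catalogue, transcripts with planted target sites,
# and null/differential count profiles.

#' Simulation configuration
#'
#' Defaults emulate desk-scale versions of the study conditions: a 100 kb
#' surrogate genome with 20 valid planted hairpins, mature counts of at
#' least 50 under a heavy-tailed (log-normal) abundance model, a 5' read
#' jitter probability of 0.1, dominant 21-nt matures with 5' U bias, 10%
#' star abundance, adapter-tagged 36-nt reads and four samples.
#'
#' @param seed Integer seed fixing all randomness.
#' @param genomeLength Genome length in bp.
#' @param gcContent Background GC fraction.
#' @param nHairpins Number of planted hairpins.
#' @param mismatchRange,bulgeRange Planted duplex mismatch (0-4) and
#'   asymmetric bulge (0-2 nt) ranges.
#' @param loopRange Terminal loop length range (nt).
#' @param matureLengthRange Mature length range (18-26 nt).
#' @param abundanceMeanlog,abundanceSdlog Log-normal abundance parameters.
#' @param minMatureCount Floor on planted mature counts.
#' @param jitterProb Probability that a planted read starts 1-2 nt off.
#' @param starFraction Star reads as a fraction of mature reads.
#' @param backgroundFraction,ncrnaFraction Background and ncRNA reads as
#'   fractions of the library size.
#' @param conservedFraction Fraction of matures drawn from the catalogue.
#' @param adapter 3' adapter appended to every insert.
#' @param readLength Emitted read length (insert plus adapter, truncated).
#' @param samples Named numeric vector of library sizes.
#' @param foldChanges Optional hairpins-by-samples fold-change matrix.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, genomeLength = 100000L,
                             gcContent = 0.4, nHairpins = 20L,
                             mismatchRange = c(0L, 3L),
                             bulgeRange = c(0L, 1L),
                             loopRange = c(15L, 40L),
                             matureLengthRange = c(20L, 22L),
                             abundanceMeanlog = log(300),
                             abundanceSdlog = 1,
                             minMatureCount = 50L,
                             jitterProb = 0.1,
                             starFraction = 0.1,
                             backgroundFraction = 0.6,
                             ncrnaFraction = 0.05,
                             conservedFraction = 0.5,
                             adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                             readLength = 36L,
                             samples = c(sample1 = 20000, sample2 = 20000,
                                         sample3 = 20000, sample4 = 20000),
                             foldChanges = NULL) {
    stopifnot(gcContent >= 0, gcContent <= 1,
              jitterProb >= 0, jitterProb <= 1,
              starFraction >= 0, starFraction <= 1,
              backgroundFraction >= 0, backgroundFraction <= 1,
              ncrnaFraction >= 0, ncrnaFraction <= 1,
              conservedFraction >= 0, conservedFraction <= 1,
              mismatchRange[1] >= 0L, mismatchRange[2] <= 4L,
              bulgeRange[1] >= 0L, bulgeRange[2] <= 2L,
              matureLengthRange[1] >= 18L, matureLengthRange[2] <= 26L,
              genomeLength >= nHairpins * 200L)
    structure(as.list(environment()), class = "SimulationConfig")
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A")

# A base that can neither Watson-Crick pair nor wobble with any of
# `counters` (falls back to avoiding the first counter only).
nonpairing_base <- function(counters) {
    banned_for <- function(ct) {
        b <- complement_base[[ct]]
        if (ct == "G") b <- c(b, "T")
        if (ct == "T") b <- c(b, "G")
        b
    }
    ok <- setdiff(c("A", "C", "G", "T"),
                  unique(unlist(lapply(counters, banned_for))))
    if (length(ok) == 0L)
        ok <- setdiff(c("A", "C", "G", "T"), banned_for(counters[[1]]))
    if (length(ok) == 1L) ok else sample(ok, 1L)
}

#' Synthesize a hairpin precursor around a mature sequence
#'
#' Builds 5'arm(mature)-loop-3'arm(star) where the star is the reverse
#' complement of the mature mutated at `mismatches` positions (choosing
#' bases that cannot pair or wobble) plus an optional asymmetric bulge,
#' with 2-nt 3' overhangs on both duplex ends by construction.
#'
#' @param mature Mature sequence, 18-26 nt (DNA alphabet).
#' @param mismatches Planted duplex mismatches (0-4).
#' @param bulge Asymmetric star-side bulge length (0-3 nt).
#' @param loopLength Terminal loop length (>= 3 nt).
#' @return List with `precursor`, `matureOffset`, `matureLength`,
#'   `starOffset`, `starLength`, `star`, `mismatches`, `bulge`.
#' @export
synthesizePrecursor <- function(mature, mismatches = 0L, bulge = 0L,
                                loopLength = 20L) {
    mature <- toupper(toDNA(mature))
    L <- nchar(mature)
    stopifnot(L >= 18L, L <= 26L, loopLength >= 3L)
    if (mismatches > 4L)
        stop("requested mismatches outside the plant-criteria design range")
    if (bulge > 3L)
        stop("requested bulge outside the design range")
    # the emitted precursor must fold back to the planted register under
    # the baseline engine; draws where an alternative structure wins are
    # rejected and redrawn
    for (try in seq_len(200L)) {
        hp <- synthesize_precursor_once(mature, mismatches, bulge,
                                        loopLength)
        f <- foldBaseline(hp$precursor)
        st <- findStar(f$structure, hp$matureOffset, hp$matureLength)
        if (is.null(st)) next
        if (abs(st$starOffset - hp$starOffset) > 2L ||
            abs(st$starLength - hp$starLength) > 2L) next
        dup <- duplexReport(f$structure, hp$matureOffset, hp$matureLength,
                            st$starOffset, st$starLength)
        if (dup$mismatches > mismatches ||
            dup$mismatches < min(1L, mismatches) ||
            dup$largest_asymmetric_bulge != bulge) next
        if (bulge <= 2L) {
            crit <- checkPlantCriteria(f$structure, hp$matureOffset,
                                       hp$matureLength, st$starOffset,
                                       st$starLength, duplex = dup)
            if (!crit$accepted) next
        }
        return(hp)
    }
    stop("infeasible precursor parameter combination")
}

synthesize_precursor_once <- function(mature, mismatches, bulge,
                                      loopLength) {
    L <- nchar(mature)
    mvec <- strsplit(mature, "")[[1]]
    core <- strsplit(revcomp(substr(mature, 1L, L - 2L)), "")[[1]]
    # star core position j pairs mature position L-1-j (1-based); planted
    # mismatches are spread out and mutated to bases that cannot pair the
    # facing mature neighbourhood, so the planted register stays optimal
    if (mismatches > 0L) {
        repeat {
            pos <- sample(3:(L - 4L), mismatches)
            if (mismatches == 1L || min(diff(sort(pos))) >= 3L) break
        }
        for (j in pos) {
            near <- mvec[max(1L, L - 3L - j):min(L, L + 1L - j)]
            core[j] <- nonpairing_base(near)
        }
    }
    if (bulge > 0L) {
        at <- sample(4:(L - 5L), 1L)
        # bulged bases must not pair with the mature bases they face
        near <- mvec[max(1L, L - 2L - at):min(L, L + 1L - at)]
        core <- append(core, vapply(seq_len(bulge), function(z)
            nonpairing_base(near), character(1)), after = at)
    }
    # boundary bases are chosen unable to pair with the duplex ends so the
    # baseline folder reproduces the planted register exactly
    overhang <- c(nonpairing_base(mvec[c(1L, 2L)]),
                  nonpairing_base(mvec[c(1L, 2L)]))
    star <- paste(c(core, overhang), collapse = "")
    loop_v <- strsplit(random_dna(loopLength), "")[[1]]
    loop_v[loopLength] <- nonpairing_base(mvec[c(L - 1L, L)])
    loop_v[loopLength - 1L] <- nonpairing_base(mvec[c(L - 1L, L)])
    loop <- paste(loop_v, collapse = "")
    list(precursor = paste0(mature, loop, star),
         matureOffset = 0L, matureLength = L,
         starOffset = L + loopLength,
         starLength = nchar(star),
         star = star, mismatches = as.integer(mismatches),
         bulge = as.integer(bulge))
}

#' Simulate a known-miRNA catalogue
#'
#' Random mature sequences with a guaranteed minimum pairwise Hamming
#' distance, named miRBase-style (miR<k><variant letter>) so families are
#' parseable.
#'
#' @param n Number of entries.
#' @param length Sequence length (default 21).
#' @param minDist Minimum pairwise Hamming distance (default 5).
#' @return A catalogue data.frame (`name`, `family`, `species`,
#'   `sequence`).
#' @export
simulateCatalogue <- function(n = 30L, length = 21L, minDist = 5L) {
    seqs <- character(0)
    tries <- 0L
    while (length(seqs) < n) {
        tries <- tries + 1L
        if (tries > 1000L * n) stop("catalogue generation failed")
        s <- paste0("T", random_dna(length - 1L))
        if (all(vapply(seqs, function(o) hamming(s, o) >= minDist,
                       logical(1))))
            seqs <- c(seqs, s)
    }
    fam_no <- 100L + seq_len(n)
    data.frame(name = sprintf("miR%d%s", fam_no,
                              letters[(seq_len(n) - 1L) %% 3L + 1L]),
               family = sprintf("miR%d", fam_no),
               species = "syn", sequence = seqs, stringsAsFactors = FALSE)
}

#' Simulate an ncRNA reference set
#'
#' @param n Entries per class.
#' @param lengthRange Reference sequence lengths.
#' @return A data.frame (`name`, `class`, `sequence`).
#' @export
simulateNcRNA <- function(n = 2L, lengthRange = c(80L, 200L)) {
    classes <- c("rRNA", "tRNA", "snRNA", "snoRNA")
    rows <- lapply(classes, function(cl) {
        data.frame(name = sprintf("%s_%d", cl, seq_len(n)), class = cl,
                   sequence = vapply(seq_len(n), function(i)
                       random_dna(sample(lengthRange[1]:lengthRange[2], 1L)),
                       character(1)),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Generate a genome with planted hairpins and full ground truth
#'
#' @param config A [simulationConfig()].
#' @return A list of class `Simulation` with `genome` (DNAStringSet,
#'   one sequence "chr1"), `truth` (data.frame, one row per hairpin),
#'   `catalogue`, `ncrna`, `foldChanges` (hairpins x samples) and
#'   `config`.
#' @export
generateGenome <- function(config = simulationConfig()) {
    with_seed(config$seed, {
        catalogue <- simulateCatalogue()
        ncrna <- simulateNcRNA()
        n <- config$nHairpins
        conserved <- if (n > 0L)
            stats::runif(n) < config$conservedFraction else logical(0)
        cat_pick <- sample(nrow(catalogue), sum(conserved))
        matures <- character(n)
        ci <- 0L
        for (i in seq_len(n)) {
            if (conserved[i]) {
                ci <- ci + 1L
                matures[i] <- catalogue$sequence[cat_pick[ci]]
            } else {
                # invented matures stay >2 mismatches from the catalogue
                repeat {
                    len <- sample(config$matureLengthRange[1]:
                                  config$matureLengthRange[2], 1L)
                    first <- sample(c("T", "A", "C", "G"), 1L,
                                    prob = c(0.65, 0.12, 0.115, 0.115))
                    s <- paste0(first, random_dna(len - 1L))
                    if (is.null(matchKnown(s, catalogue, maxMM = 2L,
                                           maxShift = 2L))) break
                }
                matures[i] <- s
            }
        }
        hp <- lapply(seq_len(n), function(i) {
            synthesizePrecursor(
                matures[i],
                mismatches = sample(config$mismatchRange[1]:
                                    config$mismatchRange[2], 1L),
                bulge = sample(config$bulgeRange[1]:
                               config$bulgeRange[2], 1L),
                loopLength = sample(config$loopRange[1]:
                                    config$loopRange[2], 1L))
        })
        genome <- strsplit(random_dna(config$genomeLength,
                                      config$gcContent), "")[[1]]
        # non-overlapping placement with 100 bp clearance
        placed <- matrix(numeric(0), ncol = 2)
        starts <- integer(n); strands <- character(n)
        for (i in seq_len(n)) {
            plen <- nchar(hp[[i]]$precursor)
            ok <- FALSE
            for (try in seq_len(1000L)) {
                pos <- sample.int(config$genomeLength - plen, 1L) - 1L
                if (nrow(placed) == 0L ||
                    all(pos + plen + 100L <= placed[, 1] |
                        pos >= placed[, 2] + 100L)) { ok <- TRUE; break }
            }
            if (!ok) stop("hairpin placement failed")
            placed <- rbind(placed, c(pos, pos + plen))
            starts[i] <- pos
            strands[i] <- sample(c("+", "-"), 1L)
            emb <- if (strands[i] == "+") hp[[i]]$precursor
                   else revcomp(hp[[i]]$precursor)
            genome[(pos + 1L):(pos + plen)] <- strsplit(emb, "")[[1]]
        }
        base_count <- if (n > 0L)
            pmax(config$minMatureCount,
                 round(stats::rlnorm(n, config$abundanceMeanlog,
                                     config$abundanceSdlog)))
            else numeric(0)
        truth <- data.frame(
            id = if (n > 0L) sprintf("hp%02d", seq_len(n)) else character(0),
            seq_id = rep("chr1", n),
            start = starts,
            end = starts + vapply(hp, function(h) nchar(h$precursor),
                                  integer(1)),
            strand = strands,
            mature = matures,
            mature_offset = vapply(hp, `[[`, integer(1), "matureOffset"),
            star = vapply(hp, `[[`, character(1), "star"),
            star_offset = vapply(hp, `[[`, integer(1), "starOffset"),
            mismatches = vapply(hp, `[[`, integer(1), "mismatches"),
            bulge = vapply(hp, `[[`, integer(1), "bulge"),
            conserved = conserved,
            base_count = as.numeric(base_count),
            stringsAsFactors = FALSE)
        # genomic start of the mature tag
        truth$mature_gstart <- ifelse(
            truth$strand == "+", truth$start + truth$mature_offset,
            truth$end - truth$mature_offset - nchar(truth$mature))
        fc <- config$foldChanges
        if (is.null(fc))
            fc <- matrix(1, nrow = n, ncol = length(config$samples),
                         dimnames = list(truth$id, names(config$samples)))
        g <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
        names(g) <- "chr1"
        structure(list(genome = g, truth = truth, catalogue = catalogue,
                       ncrna = ncrna, foldChanges = fc, config = config),
                  class = "Simulation")
    })
}

# Sense-strand insert of length `len` whose 5' end sits at `offset5`
# relative to the hairpin's own 5' end (genomic extraction honouring
# strand).
hairpin_insert <- function(genome_chr, rec, offset5, len) {
    if (rec$strand == "+") {
        st <- rec$start + offset5
        substr(genome_chr, st + 1L, st + len)
    } else {
        en <- rec$end - offset5
        revcomp(substr(genome_chr, en - len + 1L, en))
    }
}

#' Simulate one sample's read library
#'
#' Planted mature and star reads (abundance times the sample fold-change,
#' with 5' jitter), background genome fragments and ncRNA fragments, each
#' read carrying the adapter 3' of the insert, uniform high qualities.
#'
#' @param sim A `Simulation` from [generateGenome()].
#' @param sampleName One of the configured sample names.
#' @return List with `reads` (data.frame `id`, `sequence`, `quality`) and
#'   `truthCounts` (data.frame `sequence`, `count`: expected collapsed
#'   counts of un-jittered planted matures/stars).
#' @export
simulateSample <- function(sim, sampleName) {
    config <- sim$config
    stopifnot(sampleName %in% names(config$samples))
    lib <- config$samples[[sampleName]]
    seed <- config$seed + match(sampleName, names(config$samples))
    with_seed(seed, {
        chr <- as.character(sim$genome[[1]])
        inserts <- character(0)
        truth_rows <- list()
        for (i in seq_len(nrow(sim$truth))) {
            rec <- sim$truth[i, ]
            fc <- sim$foldChanges[rec$id, sampleName]
            n_m <- round(rec$base_count * fc)
            if (n_m < 1L) next
            L <- nchar(rec$mature)
            jit <- stats::runif(n_m) < config$jitterProb
            shifts <- integer(n_m)
            shifts[jit] <- sample(c(-2L, -1L, 1L, 2L), sum(jit),
                                  replace = TRUE)
            m_off <- rec$mature_offset
            ins <- vapply(shifts, function(sh)
                hairpin_insert(chr, rec, m_off + sh, L), character(1))
            inserts <- c(inserts, ins)
            n_s <- round(n_m * config$starFraction)
            if (n_s >= 1L) {
                s_ins <- hairpin_insert(chr, rec, rec$star_offset,
                                        nchar(rec$star))
                inserts <- c(inserts, rep(s_ins, n_s))
            } else s_ins <- NA_character_
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                id = rec$id,
                sequence = hairpin_insert(chr, rec, m_off, L),
                count = sum(!jit), role = "mature",
                stringsAsFactors = FALSE)
            if (n_s >= 1L)
                truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                    id = rec$id, sequence = s_ins, count = n_s,
                    role = "star", stringsAsFactors = FALSE)
        }
        n_bg <- round(lib * config$backgroundFraction)
        if (n_bg > 0L) {
            lens <- sample(18:26, n_bg, replace = TRUE,
                           prob = c(1, 1, 1, 3, 1.5, 1, 2.5, 1, 1))
            pos <- vapply(lens, function(l)
                sample.int(config$genomeLength - l, 1L), integer(1))
            frag <- substring(chr, pos + 1L, pos + lens)
            neg <- stats::runif(n_bg) < 0.5
            frag[neg] <- revcomp(frag[neg])
            inserts <- c(inserts, frag)
        }
        n_nc <- round(lib * config$ncrnaFraction)
        if (n_nc > 0L) {
            ref_i <- sample(nrow(sim$ncrna), n_nc, replace = TRUE)
            frag <- vapply(ref_i, function(ri) {
                rs <- sim$ncrna$sequence[ri]
                l <- sample(18:26, 1L)
                p <- sample.int(nchar(rs) - l, 1L)
                substr(rs, p + 1L, p + l)
            }, character(1))
            inserts <- c(inserts, frag)
        }
        reads <- substr(paste0(inserts, config$adapter), 1L,
                        config$readLength)
        truthCounts <- do.call(rbind, truth_rows)
        if (is.null(truthCounts))
            truthCounts <- data.frame(id = character(),
                                      sequence = character(),
                                      count = integer(), role = character(),
                                      stringsAsFactors = FALSE)
        list(reads = data.frame(
                 id = sprintf("%s_r%06d", sampleName, seq_along(reads)),
                 sequence = reads,
                 quality = strrep("I", nchar(reads)),
                 stringsAsFactors = FALSE),
             truthCounts = truthCounts)
    })
}

#' Write simulated reads as FASTQ
#'
#' @param reads Read data.frame from [simulateSample()].
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
writeSimulatedFastq <- function(reads, path) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$sequence,
                               "+", reads$quality)), path)
    invisible(path)
}

#' Plant a target site of known penalty into a random transcript
#'
#' Starts from the perfect reverse-complement site and applies edits whose
#' scheme contributions sum exactly to `desiredPenalty` (non-core G:U 0.5,
#' non-core mismatch 1, core G:U 1, core mismatch 2).
#'
#' @param mirna miRNA sequence (RNA or DNA).
#' @param desiredPenalty Target penalty (multiple of 0.5).
#' @param transcriptLength Background transcript length.
#' @param scheme A [scoringScheme()].
#' @return List with `transcript`, `start` (0-based site start), `site`,
#'   `penalty`.
#' @export
plantTarget <- function(mirna, desiredPenalty, transcriptLength = 300L,
                        scheme = scoringScheme()) {
    m <- strsplit(toupper(toDNA(mirna)), "")[[1]]
    L <- length(m)
    stopifnot(transcriptLength >= L + 10L)
    if (desiredPenalty < 0 || (desiredPenalty * 2) %% 1 != 0)
        stop("penalty not representable by the scheme's edit contributions")
    site <- strsplit(revcomp(paste(m, collapse = "")), "")[[1]]
    # site position j pairs miRNA position L - j + 1
    noncore <- setdiff(seq_len(L), scheme$coreRange)
    core <- intersect(seq_len(L), scheme$coreRange)
    can_gu <- m %in% c("G", "T")
    remaining <- desiredPenalty
    edits <- list()  # (mirna position, type)
    used <- integer(0)
    pick <- function(pool) {
        p <- setdiff(pool, used)
        if (length(p) == 0L) stop("penalty not achievable for this miRNA")
        p[1L]
    }
    take <- function(i, type, contrib) {
        used <<- c(used, i)
        edits[[length(edits) + 1L]] <<- list(i = i, type = type)
        remaining <<- remaining - contrib
    }
    if ((remaining * 2) %% 2 == 1)  # an odd half-unit needs a non-core G:U
        take(pick(noncore[can_gu[noncore]]), "gu", scheme$gu)
    # non-core mismatches (1), then core mismatches (2), then core G:U (1)
    while (remaining >= scheme$mismatch &&
           remaining < 2 * scheme$mismatch * length(setdiff(core, used)) +
               scheme$mismatch &&
           length(setdiff(noncore, used)) > 0L)
        take(pick(noncore), "mm", scheme$mismatch)
    while (remaining >= 2 * scheme$mismatch &&
           length(setdiff(core, used)) > 0L)
        take(pick(core), "mm", 2 * scheme$mismatch)
    while (remaining >= scheme$gu * scheme$coreMultiplier &&
           length(setdiff(core[can_gu[core]], used)) > 0L)
        take(pick(core[can_gu[core]]), "gu",
             scheme$gu * scheme$coreMultiplier)
    if (remaining > 0) stop("penalty not achievable for this miRNA")
    for (e in edits) {
        j <- L - e$i + 1L
        if (e$type == "gu") {
            site[j] <- if (m[e$i] == "G") "T" else "G"
        } else {
            site[j] <- nonpairing_base(m[e$i])
        }
    }
    site_str <- paste(site, collapse = "")
    bg <- random_dna(transcriptLength)
    start <- sample.int(transcriptLength - L - 1L, 1L)
    transcript <- paste0(substr(bg, 1L, start), site_str,
                         substr(bg, start + L + 1L, transcriptLength))
    list(transcript = transcript, start = start, site = site_str,
         penalty = desiredPenalty)
}

#' Simulate null or differential count profiles
#'
#' Poisson counts around library-size-scaled common rates; designated tags
#' carry fold-changes in designated samples.
#'
#' @param nTags Number of tags.
#' @param samples Named numeric vector of library sizes.
#' @param foldChanges Optional nTags x samples matrix (default all 1 =
#'   null).
#' @param baseRate Per-read base rate of each tag (default 5e-4, i.e. 500
#'   per million).
#' @param seed Integer seed.
#' @return List with `profile` (a [CountProfile-class]) and `truth`
#'   (logical vector: tag carries a fold-change).
#' @export
simulateProfiles <- function(nTags, samples, foldChanges = NULL,
                             baseRate = 5e-4, seed = 1L) {
    stopifnot(length(samples) >= 2L)
    if (is.null(foldChanges))
        foldChanges <- matrix(1, nrow = nTags, ncol = length(samples))
    with_seed(seed, {
        counts <- matrix(0L, nrow = nTags, ncol = length(samples),
                         dimnames = list(
                             if (nTags > 0L) sprintf("tag%04d", seq_len(nTags))
                             else NULL,
                             names(samples)))
        for (t in seq_len(nTags)) for (s in seq_along(samples)) {
            counts[t, s] <- stats::rpois(
                1L, samples[[s]] * baseRate * foldChanges[t, s])
        }
        profile <- countProfile(
            counts, totals = pmax(as.numeric(samples), colSums(counts)))
        truth <- if (nTags > 0L)
            apply(foldChanges != 1, 1L, any) else logical(0)
        list(profile = profile, truth = truth)
    })
}
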