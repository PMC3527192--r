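# RNA secondary-structure engines.  The baseline engine is a deterministic
# maximum-weight non-crossing pairing (GC=3, AU=2, GU=1, minimum loop 3)
# with a fixed traceback, so tests and results do not depend on external
# thermodynamic parameter tables.  A thermodynamic engine (ViennaRNA's
# RNAfold, if on PATH) can be plugged in.

#' Fold a sequence with the baseline engine
#'
#' Maximum-weight non-crossing base pairing with weights GC=3, AU=2, GU=1
#' and a minimum hairpin loop of 3 unpaired bases.  The reported energy is
#' the negated total pair weight (arbitrary units).  The traceback is
#' deterministic: the leftmost base pairs the largest partner attaining the
#' optimum, bifurcating at the smallest split point.
#'
#' @param sequence RNA or DNA sequence (T and U are equivalent).
#' @return List with `structure` (dot-bracket) and `energy`.
#' @examples
#' foldBaseline("GGGAAAACCC")  # (((....))), energy -9
#' @export
foldBaseline <- function(sequence) {
    if (!nzchar(sequence)) stop("empty sequence")
    if (!grepl("^[ACGTUacgtu]+$", sequence))
        stop("sequence must be over the {A,C,G,T,U} alphabet")
    nussinov_fold_cpp(sequence, 3L)
}

#' Construct a folding engine
#'
#' @param name "baseline" (default, deterministic weighted pairing) or
#'   "vienna" (RNAfold minimum free energy; requires the RNAfold binary).
#' @return List with elements `fold` (function sequence ->
#'   list(structure, energy)), `name` and `thermodynamic`.
#' @export
foldingEngine <- function(name = c("baseline", "vienna")) {
    name <- match.arg(name)
    if (name == "baseline") {
        list(fold = foldBaseline, name = "baseline", thermodynamic = FALSE)
    } else {
        if (Sys.which("RNAfold") == "")
            stop("RNAfold binary not found on PATH")
        fold <- function(sequence) {
            out <- system2("RNAfold", args = "--noPS",
                           input = toRNA(toupper(sequence)), stdout = TRUE)
            line <- out[2L]
            db <- sub("^([.()]+).*$", "\\1", line)
            en <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
            list(structure = db, energy = en)
        }
        list(fold = fold, name = "vienna", thermodynamic = TRUE)
    }
}

# Partner table of a dot-bracket string: integer vector, 1-based partner
# position or 0 when unpaired.
pairTable <- function(structure) {
    ch <- strsplit(structure, "")[[1]]
    n <- length(ch)
    p <- integer(n)
    stack <- integer(0)
    for (i in seq_len(n)) {
        if (ch[i] == "(") stack <- c(stack, i)
        else if (ch[i] == ")") {
            if (length(stack) == 0L) stop("unbalanced structure")
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            p[i] <- j; p[j] <- i
        }
    }
    if (length(stack)) stop("unbalanced structure")
    p
}
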