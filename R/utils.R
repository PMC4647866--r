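# shared internal helpers

# fixed 12-significant-digit formatting used by every writer, so repeated
# runs are byte-identical
.fmtNum <- function(x) {
    out <- sprintf("%.12g", x)
    out[is.na(x)] <- ""
    out
}

# errors that should surface as usage errors (CLI exit code 2)
.usageStop <- function(fmt, ...) {
    stop(structure(class = c("usageError", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# positive-slope rank (1 = largest value), ties averaged
.centralityRank <- function(v) rank(-v, ties.method = "average")
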