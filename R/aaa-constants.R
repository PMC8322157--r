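# Shared constants (file sorts first so load-time users see them).

.CONTEXTS <- c("CG", "CHG", "CHH")
.H_BASES <- c("A", "C", "T")
.STATUS_LEVELS <- c("U", "I", "M")
.MODEL_KINDS <- c("ABneutral", "ABmm", "ABuu", "ABnull")

# per-region divergence weights on {U, I, M}: discordant U/M pairs count 1,
# pairs differing through I count 0.5, identical calls count 0
.DIV_W <- matrix(c(0, 0.5, 1,
                   0.5, 0, 0.5,
                   1, 0.5, 0), 3L, 3L,
                 dimnames = list(.STATUS_LEVELS, .STATUS_LEVELS))
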