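# Printed reference matrices for the toy EGF/TNFA example: the measured
# data and the reachable-signals matrix of the trained model.
toy_signal_names <- c("RAF-1", "ERK", "AP1", "GSK-3", "P38", "NFKB", "IKK",
                      "MAP3K1", "MAP3K7", "PI3K")

toy_reachable_reference <- function() {
  experiment_matrix(rbind(EGF  = c(1, 1, 1, 1, 1, 0, 0, 1, 0, 1),
                          TNFA = c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1)),
                    c("EGF", "TNFA"), toy_signal_names)
}
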