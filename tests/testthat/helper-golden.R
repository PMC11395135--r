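# Frozen expected values for regression tests.
#
# Leave-out ranks of the 10 planted-module genes on the seed-7 synthetic
# fixture (n = 100, L = 3, module_size = 10, p_in = 0.15, attachment_m = 2,
# layer_overlap = 0.3), default centrality walker. Computed once from a
# verified run and frozen; the genes are, in sorted order:
# g008 g015 g031 g042 g066 g067 g083 g088 g090 g092.
GOLDEN_LOOCV_RANKS <- c(3L, 25L, 2L, 2L, 1L, 11L, 3L, 3L, 2L, 4L)
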