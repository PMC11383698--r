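# Frozen reference values of the default rescale table: mean lowest
# non-zero voxel value of thresholded synthetic X-ray blobs per resolution
# bin (edges 1.0--4.0 A in 0.5 A steps). Regenerate with
# build_rescale_table(seed = 20240101) after changing the blob generator.
DEFAULT_RESCALE_REFERENCE <- c(2.028616, 3.984039, 6.701429, 9.957523,
                               13.510741, 17.145880)
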