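segment_id	anchor_index
TRBV2	45
TRBV4-1	45
TRBV4-3	45
TRBV5-1	45
TRBV6-5	45
TRBV7-2	45
TRBV7-6	45
TRBV9	45
TRBV12-3	45
TRBV19	45
TRBV20-1	45
TRBV28	45
TRBJ1-1	12
TRBJ1-2	12
TRBJ1-3	12
TRBJ1-4	12
TRBJ1-5	12
TRBJ1-6	12
TRBJ2-1	12
TRBJ2-2	12
TRBJ2-3	12
TRBJ2-4	12
TRBJ2-5	12
TRBJ2-6	12
TRBJ2-7	12
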