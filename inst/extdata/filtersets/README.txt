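Published reference range-gate filter sets for the seven-class phytoplankton
classification worked example: per-class [min, max] gates fitted from 25 and
from 50 randomly selected training images, and the narrowed "intersection"
filter set (highest minimum, lowest maximum per feature). Sizes (diameterABD,
length, perimeter) in micrometres; signal features in 8-bit levels.
These files are inputs to the worked-example tests that re-derive the
intersection column from the 25/50 columns.
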