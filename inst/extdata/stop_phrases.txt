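# Filler phrases and articles stripped from raw AUT responses before
# equivalence matching. One phrase per line; longest phrases are matched
# first. Curators can extend this list.
used for
use for
used as
use as
it can be a
it can be
can be
you can
to make
a
an
the
to
for
as
it
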