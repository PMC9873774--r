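{
  "brick": ["weight", "building", "tool", "weapon", "art", "container", "exercise", "furniture"],
  "hat": ["container", "clothing", "decoration", "toy", "signal", "protection", "collection", "art"],
  "hammer": ["tool", "weapon", "weight", "instrument", "art", "exercise", "lever", "decoration"],
  "newspaper": ["packing", "cleaning", "fuel", "art", "insulation", "protection", "toy", "information"],
  "shoe": ["container", "tool", "decoration", "weapon", "toy", "plant-pot", "protection", "art"]
}
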