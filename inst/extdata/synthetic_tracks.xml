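<?xml version="1.0" encoding="UTF-8"?>
<Tracks nTracks="3" frameInterval="0.03003" spaceUnits="micron" timeUnits="s">
  <particle nSpots="12">
    <detection t="0" x="0.004098" y="-0.024264" z="0"/>
    <detection t="1" x="0.037784" y="0.009593" z="0"/>
    <detection t="2" x="0.111420" y="-0.404408" z="0"/>
    <detection t="3" x="0.143427" y="-0.615611" z="0"/>
    <detection t="4" x="0.224039" y="-0.614716" z="0"/>
    <detection t="5" x="0.159101" y="-0.639303" z="0"/>
    <detection t="6" x="0.154621" y="-0.630480" z="0"/>
    <detection t="7" x="0.027082" y="-0.551826" z="0"/>
    <detection t="8" x="0.089344" y="-0.544935" z="0"/>
    <detection t="9" x="0.045598" y="-0.790276" z="0"/>
    <detection t="10" x="-0.166705" y="-0.884322" z="0"/>
    <detection t="11" x="-0.283047" y="-1.208291" z="0"/>
  </particle>
  <particle nSpots="12">
    <detection t="0" x="-0.012672" y="-0.023895" z="0"/>
    <detection t="1" x="0.164469" y="-0.219762" z="0"/>
    <detection t="2" x="0.290408" y="-0.497996" z="0"/>
    <detection t="3" x="-0.139266" y="-0.650876" z="0"/>
    <detection t="4" x="-0.694125" y="-0.792275" z="0"/>
    <detection t="5" x="-0.654114" y="-0.533567" z="0"/>
    <detection t="6" x="-0.716610" y="-0.512000" z="0"/>
    <detection t="7" x="-1.035615" y="-0.789503" z="0"/>
    <detection t="8" x="-0.954969" y="-0.707820" z="0"/>
    <detection t="9" x="-0.881390" y="-0.664978" z="0"/>
    <detection t="10" x="-0.719092" y="-0.700129" z="0"/>
    <detection t="11" x="-0.574876" y="-0.872226" z="0"/>
  </particle>
  <particle nSpots="12">
    <detection t="0" x="-0.001123" y="0.001250" z="0"/>
    <detection t="1" x="-0.007577" y="0.014890" z="0"/>
    <detection t="2" x="-0.032716" y="-0.074373" z="0"/>
    <detection t="3" x="-0.008447" y="-0.061484" z="0"/>
    <detection t="4" x="0.045400" y="-0.146336" z="0"/>
    <detection t="5" x="0.181431" y="-0.288587" z="0"/>
    <detection t="6" x="0.080551" y="-0.295977" z="0"/>
    <detection t="7" x="-0.144699" y="-0.313821" z="0"/>
    <detection t="8" x="0.107834" y="-0.418009" z="0"/>
    <detection t="9" x="0.344705" y="-0.363400" z="0"/>
    <detection t="10" x="0.379188" y="-0.536527" z="0"/>
    <detection t="11" x="0.374318" y="-0.778825" z="0"/>
  </particle>
</Tracks>
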