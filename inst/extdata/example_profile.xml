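<profile mode="sum" top_n="25">
  <criterion property="MW" min="200" max="450" gradient="0.005" hard="false"/>
  <criterion property="clogP" min="-1" max="3" gradient="0.1" hard="false"/>
  <criterion property="TPSA" min="40" max="120" gradient="0.01" hard="false"/>
  <criterion property="PFI_proxy" max="6" gradient="0.2" hard="false"/>
</profile>
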