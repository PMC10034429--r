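<?xml version="1.0"?>
<!-- Hand-written synthetic KGML fragment modelled on the lower part of
     glycolysis (phosphofructokinase, aldolase, GAPDH); used for parser
     smoke tests.  Not real KEGG data. -->
<pathway name="path:syn00010" org="syn" number="00010" title="synthetic lower glycolysis">
  <entry id="1" name="syn:pfkA" type="gene" reaction="rn:R04779"/>
  <entry id="2" name="syn:fbaA syn:fbaB" type="gene" reaction="rn:R01070"/>
  <entry id="3" name="syn:gapA" type="gene" reaction="rn:R01061"/>
  <entry id="101" name="ec:2.7.1.11" type="enzyme" reaction="rn:R04779"/>
  <entry id="102" name="ec:4.1.2.13" type="enzyme" reaction="rn:R01070"/>
  <entry id="103" name="ec:1.2.1.12" type="enzyme" reaction="rn:R01061"/>
  <entry id="301" name="cpd:C00085" type="compound"/>
  <entry id="302" name="cpd:C00354" type="compound"/>
  <entry id="303" name="cpd:C00118" type="compound"/>
  <entry id="304" name="cpd:C00236" type="compound"/>
  <reaction id="201" name="rn:R04779" type="irreversible">
    <substrate id="301" name="cpd:C00085"/>
    <product id="302" name="cpd:C00354"/>
  </reaction>
  <reaction id="202" name="rn:R01070" type="reversible">
    <substrate id="302" name="cpd:C00354"/>
    <product id="303" name="cpd:C00118"/>
  </reaction>
  <reaction id="203" name="rn:R01061" type="reversible">
    <substrate id="303" name="cpd:C00118"/>
    <product id="304" name="cpd:C00236"/>
  </reaction>
</pathway>
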