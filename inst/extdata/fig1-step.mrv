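<cml>
  <MDocument>
    <MChemicalStruct>
      <molecule molID="m1">
        <atomArray
            atomID="a1 a2 a3 a4 a5 a6 a7 a8 a9 a10 a11 a12 a13 a14 a15 a16 a17 a18 a19 a20 a21"
            elementType="C O C H C H O O C H O C O C O C O H C O C"
            formalCharge="0 0 0 0 0 0 0 0 0 0 0 0 -1 0 0 0 0 0 0 0 0"/>
        <bondArray>
          <bond id="b1" atomRefs2="a1 a2" order="1"/>
          <bond id="b2" atomRefs2="a2 a3" order="1"/>
          <bond id="b3" atomRefs2="a1 a4" order="1"/>
          <bond id="b4" atomRefs2="a1 a5" order="1"/>
          <bond id="b5" atomRefs2="a5 a6" order="1"/>
          <bond id="b6" atomRefs2="a5 a7" order="1"/>
          <bond id="b7" atomRefs2="a1 a8" order="1"/>
          <bond id="b8" atomRefs2="a8 a9" order="1"/>
          <bond id="b9" atomRefs2="a9 a10" order="1"/>
          <bond id="b10" atomRefs2="a9 a11" order="1"/>
          <bond id="b11" atomRefs2="a9 a12" order="1"/>
          <bond id="b12" atomRefs2="a13 a14" order="1"/>
          <bond id="b13" atomRefs2="a14 a15" order="2"/>
          <bond id="b14" atomRefs2="a14 a16" order="1"/>
          <bond id="b15" atomRefs2="a17 a18" order="1"/>
          <bond id="b16" atomRefs2="a17 a19" order="1"/>
          <bond id="b17" atomRefs2="a19 a20" order="2"/>
          <bond id="b18" atomRefs2="a19 a21" order="1"/>
        </bondArray>
      </molecule>
    </MChemicalStruct>
    <MEFlow electrons="2" id="e1">
      <atomSetPoint atomRefs="m1.a13"/>
      <atomSetPoint atomRefs="m1.a13 m1.a1"/>
    </MEFlow>
    <MEFlow electrons="2" id="e2">
      <bondSetPoint bondRefs="b7"/>
      <atomSetPoint atomRefs="m1.a8"/>
    </MEFlow>
    <MEFlow electrons="2" id="e3">
      <atomSetPoint atomRefs="m1.a8"/>
      <atomSetPoint atomRefs="m1.a18"/>
    </MEFlow>
  </MDocument>
</cml>
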