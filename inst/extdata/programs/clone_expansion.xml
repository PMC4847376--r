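<!-- Synthetic clone-expansion program: a founder species seeds single
     cells over time; each seeded cell divides at rate 1 until the Cell
     population reaches the cap (1000), at which point the global updater
     zeroes the division rate and the clone stops expanding.  This is an
     analogue of repeated single-cell clonal expansion experiments, not a
     reproduction of any specific published run. -->
<Program>
  <ExecParams>
    <SimTime>20</SimTime>
    <Seed>1</Seed>
  </ExecParams>
  <FunHandleName>clone_expansion(species = "Cell", cap = 1000, rate = 1)</FunHandleName>
  <Rule>
    <Name>Founder</Name>
    <InitPop>1</InitPop>
    <Rate>0.5</Rate>
    <Prod>
      <Products>Founder,Cell</Products>
      <Prob>1</Prob>
    </Prod>
  </Rule>
  <Rule>
    <Name>Cell</Name>
    <InitPop>0</InitPop>
    <Rate>1</Rate>
    <Prod>
      <Products>Cell,Cell</Products>
      <Prob>1</Prob>
    </Prod>
    <InternalState>
      <Name>Gen</Name>
      <InitVal>0</InitVal>
      <FuncName>gen_increment</FuncName>
      <DupNum>1</DupNum>
    </InternalState>
  </Rule>
</Program>
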