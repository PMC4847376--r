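<?xml version="1.0" encoding="UTF-8"?>
<!-- Reference schema for the grammar-program dialect read by parse_program().
     Unknown elements are rejected by the parser.  <Prob> is a number in
     [0,1] or the sentinel "ow"; <Transition> is a species name or "{0}"
     for termination; <FuncName>/<FunHandleName> hold an updater name,
     optionally with literal arguments, e.g. ms_step(p = 0.01); state
     updaters may instead be a safe arithmetic expression over x,
     normrnd(mu, sigma), pop("Species") and time(). -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:simpleType name="ProbType">
    <xs:union>
      <xs:simpleType>
        <xs:restriction base="xs:double">
          <xs:minInclusive value="0"/>
          <xs:maxInclusive value="1"/>
        </xs:restriction>
      </xs:simpleType>
      <xs:simpleType>
        <xs:restriction base="xs:string">
          <xs:enumeration value="ow"/>
        </xs:restriction>
      </xs:simpleType>
    </xs:union>
  </xs:simpleType>

  <xs:element name="Program">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="ExecParams">
          <xs:complexType>
            <xs:all>
              <xs:element name="SimTime" type="xs:double"/>
              <xs:element name="Seed" type="xs:integer" minOccurs="0"/>
            </xs:all>
          </xs:complexType>
        </xs:element>
        <xs:element name="FunHandleName" type="xs:string" minOccurs="0"/>
        <xs:element name="Rule" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="Name" type="xs:string"/>
              <xs:element name="InitPop" type="xs:nonNegativeInteger" minOccurs="0"/>
              <xs:element name="Rate" type="xs:double"/>
              <xs:element name="Prod" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <!-- Products: comma-separated species names; empty for
                         the termination group (phi); at most two names. -->
                    <xs:element name="Products" type="xs:string"/>
                    <xs:element name="Prob" type="ProbType"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="InternalState" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="Name" type="xs:string"/>
                    <xs:element name="InitVal" type="xs:double"/>
                    <xs:element name="FuncName" type="xs:string" minOccurs="0"/>
                    <xs:element name="DupNum" type="xs:positiveInteger" minOccurs="0"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="ConditionalTransition" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="Condition" type="xs:string"/>
                    <xs:element name="Transition" type="xs:string"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <!-- Sink: declares a species with no transition rule of its own
             (it never fires); needed so outcome groups may target it. -->
        <xs:element name="Sink" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
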